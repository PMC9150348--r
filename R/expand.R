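#' Case-record probability transform
#'
#' Maps the case probability p in the source data to the probability
#' p* = p / (1 + p) that a record of the expanded (cases-doubled) data is a
#' retained case record. Strictly increasing on [0, 1] with range [0, 1/2];
#' the inverse of the odds transform: pstar(p) / (1 - pstar(p)) = p.
#'
#' @param p probability vector in [0, 1].
#' @return p / (1 + p), same length as \code{p}.
#' @export
pstar <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p must lie in [0, 1]")
  p / (1 + p)
}

#' Double the cases of a subject dataset
#'
#' Expands a subject-level dataset by appending, for every case, a duplicate
#' record with the outcome recoded to non-case. The duplicate shares the
#' subject id, covariates and sampling weight of its source record, so the
#' expanded data have N + N1 records (N1 = number of cases) of which exactly
#' N1 carry a positive outcome. A logistic regression of the modified outcome
#' then estimates log risk ratios rather than log odds ratios.
#'
#' Duplicates are appended as a block after the original records, in original
#' case order; downstream fits are permutation-invariant.
#'
#' @param data a \code{\link{subject_data}} object.
#' @return An object of class \code{expanded_data}: like \code{subject_data}
#'   but with the outcome column holding the modified outcome Y*, and an
#'   added \code{.origin} column (\code{"original"} or \code{"duplicate"}).
#' @export
expand_cases <- function(data) {
  stopifnot(inherits(data, "subject_data"))
  df <- data$df
  if (nrow(df) == 0L) stop("empty dataset")
  y <- df[[data$outcome]]
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    stop("non-binary outcome at subject_id ",
         paste(df$.id[bad], collapse = ", "))

  dup <- df[y == 1, , drop = FALSE]
  dup[[data$outcome]] <- rep(0, nrow(dup))
  df$.origin <- "original"
  if (nrow(dup)) dup$.origin <- "duplicate"
  out <- rbind(df, dup)
  rownames(out) <- NULL

  structure(
    list(df = out, outcome = data$outcome, covariates = data$covariates,
         has_stratum = isTRUE(data$has_stratum), n_source = nrow(df),
         n_source_cases = sum(y == 1)),
    class = c("expanded_data", "subject_data"))
}

#' @export
print.expanded_data <- function(x, ...) {
  cat("<expanded_data> ", nrow(x$df), " records from ", x$n_source,
      " subjects (", x$n_source_cases, " cases doubled)\n", sep = "")
  invisible(x)
}

#' Collapse an expanded dataset back to its source
#'
#' Drops the duplicate records and restores the original outcome coding,
#' recovering the source \code{subject_data} records exactly.
#'
#' @param expanded an \code{expanded_data} object.
#' @return a \code{subject_data} object.
#' @export
collapse_expanded <- function(expanded) {
  stopifnot(inherits(expanded, "expanded_data"))
  df <- expanded$df
  orig <- df[df$.origin == "original", , drop = FALSE]
  # a subject appearing twice was a case: restore Y = 1
  dup_ids <- df$.id[df$.origin == "duplicate"]
  orig[[expanded$outcome]][orig$.id %in% dup_ids] <- 1
  orig$.origin <- NULL
  structure(
    list(df = orig, outcome = expanded$outcome,
         covariates = expanded$covariates,
         has_stratum = isTRUE(expanded$has_stratum)),
    class = "subject_data")
}
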