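#' Construct a subject-level dataset
#'
#' Bundles subject-level records for risk-ratio estimation: a binary outcome,
#' a numeric covariate matrix (intercept prepended automatically), an optional
#' positive sampling weight and an optional stratum label (used for
#' frequency-matched sampling and Mantel-Haenszel stratification).
#'
#' @param data data.frame of subject-level records.
#' @param outcome name of the binary outcome column (values strictly 0/1,
#'   1 = case).
#' @param covariates character vector of covariate column names, in model
#'   order. All must be numeric. The intercept is always included as the
#'   leading design column and must not be listed.
#' @param weight optional name of a positive sampling-weight column; when
#'   absent every subject gets weight 1.
#' @param stratum optional name of a categorical stratum column.
#' @param id optional name of a unique integer subject-id column; synthesized
#'   from the row index when absent (needed to cluster residuals in the
#'   sandwich variance).
#'
#' @return An object of class \code{subject_data}: a list with elements
#'   \code{df} (the validated data.frame, with columns \code{.id},
#'   \code{.weight} and optionally \code{.stratum} added), \code{outcome},
#'   \code{covariates}.
#' @export
subject_data <- function(data, outcome, covariates, weight = NULL,
                         stratum = NULL, id = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  if (nrow(data) == 0L) stop("empty dataset")
  needed <- c(outcome, covariates, weight, stratum, id)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))

  df <- data
  df$.id <- if (is.null(id)) seq_len(nrow(df)) else df[[id]]
  if (anyDuplicated(df$.id))
    stop("subject ids are not unique")

  y <- df[[outcome]]
  bad <- which(!(y %in% c(0, 1)) | is.na(y))
  if (length(bad))
    stop("outcome must be 0/1; offending subject_id(s): ",
         paste(utils::head(df$.id[bad], 5L), collapse = ", "))

  for (v in covariates) {
    if (!is.numeric(df[[v]]))
      stop("covariate `", v, "` is not numeric")
    if (anyNA(df[[v]]))
      stop("covariate `", v, "` has missing values (rows ",
           paste(utils::head(which(is.na(df[[v]])), 5L), collapse = ", "), ")")
  }

  df$.weight <- if (is.null(weight)) rep(1, nrow(df)) else as.numeric(df[[weight]])
  if (anyNA(df$.weight) || any(df$.weight <= 0))
    stop("weights must be positive")

  if (!is.null(stratum)) {
    if (anyNA(df[[stratum]])) stop("stratum column has missing values")
    df$.stratum <- df[[stratum]]
  }

  structure(
    list(df = df, outcome = outcome, covariates = covariates,
         has_stratum = !is.null(stratum)),
    class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  n <- nrow(x$df)
  cases <- sum(x$df[[x$outcome]])
  cat("<subject_data> ", n, " subjects (", cases, " cases)\n", sep = "")
  cat("  outcome: ", x$outcome,
      "; covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  if (!all(x$df$.weight == 1)) cat("  sampling weights present\n")
  if (isTRUE(x$has_stratum)) cat("  stratum column present\n")
  invisible(x)
}

#' Number of cases in a subject dataset
#' @param data a \code{subject_data} object.
#' @return integer count of records with outcome 1.
#' @export
n_cases <- function(data) {
  stopifnot(inherits(data, "subject_data"))
  sum(data$df[[data$outcome]] == 1)
}

#' Design matrix of a subject or expanded dataset
#'
#' Leading column is the intercept constant 1, followed by the covariates in
#' declared order.
#' @param data a \code{subject_data} or \code{expanded_data} object.
#' @return numeric matrix with column names \code{(Intercept)}, covariates.
#' @export
design_matrix <- function(data) {
  df <- data$df
  X <- cbind(1, as.matrix(df[, data$covariates, drop = FALSE]))
  colnames(X) <- c("(Intercept)", data$covariates)
  X
}

#' Read a subject-level dataset from delimited text
#'
#' Reads a header-ed delimited file and validates it into a
#' \code{\link{subject_data}}. Rows with missing values in any mapped column
#' are rejected with a row-level error message.
#'
#' @param path path to the file.
#' @param outcome,covariates,weight,stratum,id column mapping, as in
#'   \code{\link{subject_data}}.
#' @param sep field separator (default comma).
#' @return a \code{subject_data} object.
#' @export
read_subject_data <- function(path, outcome, covariates, weight = NULL,
                              stratum = NULL, id = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  mapped <- c(outcome, covariates, weight, stratum, id)
  missing_cols <- setdiff(mapped, names(df))
  if (length(missing_cols))
    stop("unknown column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  na_rows <- which(rowSums(is.na(df[, mapped, drop = FALSE])) > 0)
  if (length(na_rows))
    stop(length(na_rows), " row(s) with missing mapped values (rows ",
         paste(utils::head(na_rows, 5L), collapse = ", "), ")")
  subject_data(df, outcome = outcome, covariates = covariates,
               weight = weight, stratum = stratum, id = id)
}

#' The Deddens-Petersen ten-observation example
#'
#' A classic small dataset on which standard IRLS for the log-binomial model
#' fails to converge: a binary outcome paired with a single linear exposure
#' taking values 1 to 10. Useful for exercising the doubling-of-cases
#' estimator, the Poisson robust estimator, and the constrained log-binomial
#' fit.
#'
#' @return a \code{subject_data} with outcome \code{y} and covariate \code{x}.
#' @export
deddens_petersen <- function() {
  subject_data(
    data.frame(y = c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1), x = 1:10),
    outcome = "y", covariates = "x")
}
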