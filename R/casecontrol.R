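#' Case-control sampling design
#'
#' @param ratio controls per case (positive integer m).
#' @param match_on \code{NULL} for simple random sampling of controls, or the
#'   name of a categorical column to frequency-match on (controls drawn per
#'   stratum in proportion m x cases in that stratum).
#' @param seed integer RNG seed used by \code{\link{sample_case_control}}
#'   unless overridden there.
#' @return object of class \code{sampling_design}.
#' @export
sampling_design <- function(ratio = 1L, match_on = NULL, seed = NULL) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 1 ||
      ratio != floor(ratio))
    stop("ratio must be a positive integer")
  structure(list(ratio = as.integer(ratio), match_on = match_on, seed = seed),
            class = "sampling_design")
}

#' Inverse-probability weights from stratum sampling counts
#'
#' The control weight in each stratum is the number of available (cohort)
#' non-cases divided by the number sampled; cases always carry weight 1.
#'
#' @param available named vector: non-cases available per stratum.
#' @param sampled named vector (same names): non-cases sampled per stratum.
#' @return named numeric vector of control weights per stratum.
#' @export
weights_from_counts <- function(available, sampled) {
  if (!setequal(names(available), names(sampled)) &&
      !(is.null(names(available)) && is.null(names(sampled)) &&
        length(available) == length(sampled)))
    stop("available and sampled must cover the same strata")
  if (!is.null(names(available))) sampled <- sampled[names(available)]
  if (any(sampled > available))
    stop("sampled count exceeds available non-cases in stratum ",
         paste(names(available)[sampled > available], collapse = ", "))
  if (any(sampled <= 0 & available > 0))
    stop("no controls sampled in a stratum with available non-cases")
  available / sampled
}

#' Draw a case-control sample with inverse-probability weights
#'
#' All cases enter the sample with weight 1. Controls are drawn without
#' replacement from the non-cases: m x (total cases) overall for a simple
#' random design, or m x (cases in stratum) within each matching stratum for
#' a frequency-matched design. Each control's weight is the inverse sampling
#' fraction of non-cases in its (matching) stratum. If a stratum has fewer
#' non-cases than requested, all are taken with weight 1 and a warning is
#' emitted.
#'
#' @param cohort a \code{\link{subject_data}} enumerating the cohort.
#' @param design a \code{\link{sampling_design}}.
#' @param seed integer seed (defaults to \code{design$seed}; \code{NULL}
#'   leaves the RNG stream untouched).
#' @return a \code{subject_data} of the sampled subjects with the weight
#'   column filled; attribute \code{"sampling"} holds the per-stratum
#'   available/sampled bookkeeping.
#' @export
sample_case_control <- function(cohort, design, seed = design$seed) {
  stopifnot(inherits(cohort, "subject_data"),
            inherits(design, "sampling_design"))
  df <- cohort$df
  y <- df[[cohort$outcome]]
  if (!any(y == 1)) stop("cohort has no cases")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(design$match_on)) {
    strat <- rep("(all)", nrow(df))
  } else {
    if (!design$match_on %in% names(df))
      stop("matching column `", design$match_on, "` not found")
    strat <- as.character(df[[design$match_on]])
  }

  keep <- logical(nrow(df))
  keep[y == 1] <- TRUE
  wt <- rep(1, nrow(df))
  strata <- unique(strat)
  avail <- sampled <- stats::setNames(integer(length(strata)), strata)
  for (s in strata) {
    ctrl_idx <- which(y == 0 & strat == s)
    n_cases_s <- sum(y == 1 & strat == s)
    want <- design$ratio * n_cases_s
    avail[s] <- length(ctrl_idx)
    if (want >= length(ctrl_idx)) {
      if (want > length(ctrl_idx))
        warning("stratum ", s, ": requested ", want,
                " controls but only ", length(ctrl_idx),
                " non-cases available; taking all with weight 1")
      take <- ctrl_idx
    } else {
      take <- ctrl_idx[sample.int(length(ctrl_idx), want)]
    }
    sampled[s] <- length(take)
    keep[take] <- TRUE
    if (length(take)) wt[take] <- length(ctrl_idx) / length(take)
  }

  out <- df[keep, , drop = FALSE]
  out$.weight <- wt[keep]
  rownames(out) <- NULL
  res <- structure(
    list(df = out, outcome = cohort$outcome, covariates = cohort$covariates,
         has_stratum = isTRUE(cohort$has_stratum)),
    class = "subject_data")
  attr(res, "sampling") <- data.frame(stratum = strata,
                                      available = unname(avail[strata]),
                                      sampled = unname(sampled[strata]))
  res
}
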