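#' Load a subject-level dataset (column-mapped delimited text)
#'
#' Alias of \code{\link{read_subject_data}}, the package's standard entry
#' point for delimited files. Outcome coding is strictly 0/1; labels such as
#' "case"/"control" are never auto-coerced.
#'
#' @inheritParams read_subject_data
#' @return a \code{\link{subject_data}}.
#' @export
load_dataset <- function(path, outcome, covariates, weight = NULL,
                         stratum = NULL, id = NULL, sep = ",") {
  read_subject_data(path, outcome = outcome, covariates = covariates,
                    weight = weight, stratum = stratum, id = id, sep = sep)
}

# uniform results table across methods
results_table <- function(fit) {
  if (inherits(fit, "rr_fit")) {
    ci <- fit$ci
    data.frame(term = ci$term, estimate_log = ci$estimate_log, RR = ci$RR,
               naive_SE = ci$naive_SE, robust_SE = ci$robust_SE,
               CI_low = ci$CI_low, CI_high = ci$CI_high)
  } else {
    ci <- fit$ci
    data.frame(term = ci$term, estimate_log = ci$estimate_log, RR = ci$RR,
               naive_SE = ci$SE, robust_SE = ci$SE,
               CI_low = ci$CI_low, CI_high = ci$CI_high)
  }
}

#' Fit a risk-ratio model end to end
#'
#' Orchestrates load -> (expand ->) fit -> robust covariance -> Wald CIs for
#' a chosen method, optionally writing a delimited results table and a JSON
#' file with full-precision estimates.
#'
#' @param data a \code{\link{subject_data}}, or a file path (then
#'   \code{outcome}/\code{covariates}/... are the column mapping passed to
#'   \code{\link{load_dataset}}).
#' @param method one of \code{"doubling"} (expanded-data logistic with
#'   robust SE), \code{"naive-logistic"}, \code{"log-binomial"},
#'   \code{"poisson-robust"}.
#' @param level confidence level.
#' @param output_table,output_json optional output paths (CSV / JSON).
#' @param outcome,covariates,weight,stratum,id,sep column mapping when
#'   \code{data} is a path.
#' @return invisibly, a list with \code{fit} and the results \code{table}.
#' @export
run_fit <- function(data, method = c("doubling", "naive-logistic",
                                     "log-binomial", "poisson-robust"),
                    level = 0.95, output_table = NULL, output_json = NULL,
                    outcome = NULL, covariates = NULL, weight = NULL,
                    stratum = NULL, id = NULL, sep = ",") {
  method <- match.arg(method)
  if (is.character(data)) {
    data <- load_dataset(data, outcome = outcome, covariates = covariates,
                         weight = weight, stratum = stratum, id = id,
                         sep = sep)
  }
  stopifnot(inherits(data, "subject_data"))
  fit <- switch(method,
    "doubling" = doubling_rr(data, level = level),
    "naive-logistic" = fit_naive_logistic(data, level = level),
    "log-binomial" = fit_log_binomial(data, level = level),
    "poisson-robust" = fit_poisson_robust(data, level = level))
  tab <- results_table(fit)
  if (!is.null(output_table)) {
    disp <- tab
    num <- vapply(disp, is.numeric, TRUE)
    disp[num] <- lapply(disp[num], signif, digits = 4)
    utils::write.csv(disp, output_table, row.names = FALSE)
  }
  if (!is.null(output_json)) {
    jsonlite::write_json(
      list(method = method, level = level,
           results = tab,
           converged = isTRUE(fit$converged)),
      output_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(fit = fit, table = tab))
}
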