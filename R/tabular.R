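#' Stratified 2x2 exposure-by-outcome count tables
#'
#' One row per stratum with the four cell counts: exposed cases (\code{e1}),
#' exposed non-cases (\code{e0}), unexposed cases (\code{u1}) and unexposed
#' non-cases (\code{u0}).
#'
#' @param e1,e0,u1,u0 non-negative integer count vectors, one entry per
#'   stratum.
#' @param stratum optional stratum labels.
#' @return object of class \code{stratified_table}: a data.frame of counts
#'   with derived margins \code{n_e} (exposed total), \code{n_u} (unexposed
#'   total), \code{n_cases}, \code{n}.
#' @export
stratified_table <- function(e1, e0, u1, u0, stratum = NULL) {
  k <- length(e1)
  if (k == 0L) stop("at least one stratum required")
  if (length(e0) != k || length(u1) != k || length(u0) != k)
    stop("cell count vectors must have equal length")
  cells <- cbind(e1, e0, u1, u0)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("counts must be non-negative integers")
  df <- data.frame(
    stratum = if (is.null(stratum)) seq_len(k) else stratum,
    e1 = e1, e0 = e0, u1 = u1, u0 = u0)
  df$n_e <- df$e1 + df$e0
  df$n_u <- df$u1 + df$u0
  df$n_cases <- df$e1 + df$u1
  df$n <- df$n_e + df$n_u
  structure(df, class = c("stratified_table", "data.frame"))
}

#' Read a stratified count table from long-format delimited text
#'
#' Expects columns \code{stratum}, \code{exposed} (0/1), \code{outcome}
#' (0/1) and \code{count}.
#' @param path file path.
#' @param sep field separator.
#' @return a \code{\link{stratified_table}}.
#' @export
read_count_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("stratum", "exposed", "outcome", "count")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(count ~ stratum + exposed + outcome, df, sum)
  strata <- sort(unique(agg$stratum))
  pick <- function(s, e, y) {
    v <- agg$count[agg$stratum == s & agg$exposed == e & agg$outcome == y]
    if (length(v)) v else 0L
  }
  stratified_table(
    e1 = vapply(strata, pick, 0, e = 1, y = 1),
    e0 = vapply(strata, pick, 0, e = 1, y = 0),
    u1 = vapply(strata, pick, 0, e = 0, y = 1),
    u0 = vapply(strata, pick, 0, e = 0, y = 0),
    stratum = strata)
}

#' Crude risk ratio from a single 2x2 table
#'
#' RR = (e1/n_e) / (u1/n_u) with the standard log-scale SE
#' sqrt(1/e1 - 1/n_e + 1/u1 - 1/n_u). By the doubling-of-cases identity this
#' equals the crude odds ratio of the expanded version of the same table.
#'
#' @param table a \code{stratified_table} with exactly one stratum.
#' @return list with \code{rr}, \code{log_rr}, \code{se_log} and a 95% CI
#'   (\code{ci_low}, \code{ci_high}).
#' @export
crude_rr <- function(table) {
  stopifnot(inherits(table, "stratified_table"))
  if (nrow(table) != 1L)
    stop("crude_rr expects a single stratum; see mh_rr for stratified tables")
  with(table, {
    if (n_e == 0 || n_u == 0 || u1 == 0)
      stop("undefined RR: zero exposure-group denominator or zero unexposed cases")
    rr <- (e1 / n_e) / (u1 / n_u)
    se <- sqrt(1 / e1 - 1 / n_e + 1 / u1 - 1 / n_u)
    z <- stats::qnorm(0.975)
    list(rr = rr, log_rr = log(rr), se_log = se,
         ci_low = exp(log(rr) - z * se), ci_high = exp(log(rr) + z * se))
  })
}

# shared weighted-average engine for the two MH estimators: weights times the
# per-stratum RR, with zero-weight strata contributing nothing
mh_weighted_rr <- function(table, weights) {
  keep <- weights > 0
  if (!any(keep)) stop("all Mantel-Haenszel stratum weights are zero")
  # w_k * RR_k is computed cancelling the u1 and n_e factors, so strata with
  # zero exposed cases still contribute to the numerator correctly
  num <- sum((table$e1 * table$n_u / table$n_e / table$u1 * weights)[keep])
  sum_w <- sum(weights[keep])
  num / sum_w
}

#' Mantel-Haenszel risk ratio
#'
#' Weighted average of stratum risk ratios with weights
#' w_k = u1_k * n_e_k / n_k; algebraically equal to the classical
#' sum(e1 n_u / n) / sum(u1 n_e / n). Strata with zero weight (no unexposed
#' cases or no exposed subjects) are skipped.
#'
#' @param table a \code{\link{stratified_table}}.
#' @return the MH RR point estimate (no SE is provided).
#' @export
mh_rr <- function(table) {
  stopifnot(inherits(table, "stratified_table"))
  ok <- table$n > 0 & table$n_e > 0 & table$n_u > 0 & table$u1 > 0
  w <- ifelse(ok, table$u1 * table$n_e / table$n, 0)
  mh_weighted_rr(table, w)
}

#' Mantel-Haenszel odds ratio of the expanded (cases-doubled) table
#'
#' Weighted average of the stratum risk ratios with weights
#' w*_k = u1_k * n_e_k / (n_k + cases_k); identical to the classical MH OR
#' computed on the per-stratum expanded 2x2 tables, and hence an estimator of
#' the same adjusted RR as \code{\link{mh_rr}}.
#'
#' @inheritParams mh_rr
#' @return the expanded-data MH OR point estimate.
#' @export
expanded_mh_or <- function(table) {
  stopifnot(inherits(table, "stratified_table"))
  ok <- table$n > 0 & table$n_e > 0 & table$n_u > 0 & table$u1 > 0
  w <- ifelse(ok, table$u1 * table$n_e / (table$n + table$n_cases), 0)
  mh_weighted_rr(table, w)
}

# build a stratified_table from a subject_data with a binary exposure column
# and the .stratum column (used by the simulation harness)
table_from_subjects <- function(data, exposure) {
  df <- data$df
  y <- df[[data$outcome]]
  x <- df[[exposure]]
  s <- if (!is.null(df$.stratum)) df$.stratum else rep(1L, nrow(df))
  strata <- sort(unique(s))
  cnt <- function(e, yy) vapply(strata, function(k)
    sum(s == k & x == e & y == yy), 0)
  stratified_table(e1 = cnt(1, 1), e0 = cnt(1, 0),
                   u1 = cnt(0, 1), u0 = cnt(0, 0), stratum = strata)
}
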