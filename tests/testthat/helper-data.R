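# shared fixtures, built in code

# subject data for a 2x2 table: a/Ne exposed cases, c/Nu unexposed cases
subjects_from_2x2 <- function(a, Ne, c, Nu) {
  subject_data(
    data.frame(
      y = c(rep(1, a), rep(0, Ne - a), rep(1, c), rep(0, Nu - c)),
      x = c(rep(1, Ne), rep(0, Nu))),
    outcome = "y", covariates = "x")
}

# random full-cell 2x2 table (all cells >= 1 so RR and its SE exist)
random_2x2 <- function() {
  Ne <- sample(5:60, 1); Nu <- sample(5:60, 1)
  a <- sample(seq_len(Ne - 1), 1); c <- sample(seq_len(Nu - 1), 1)
  list(a = a, Ne = Ne, c = c, Nu = Nu)
}

# random stratified table with all cells positive
random_strat_table <- function(k = 3) {
  stratified_table(
    e1 = sample(1:30, k, TRUE), e0 = sample(1:30, k, TRUE),
    u1 = sample(1:30, k, TRUE), u0 = sample(1:30, k, TRUE))
}

# random continuous-covariate dataset with a guaranteed mix of outcomes
random_subjects <- function(n = 60, p_covs = 2) {
  repeat {
    X <- matrix(stats::rnorm(n * p_covs), n, p_covs)
    eta <- -0.5 + X %*% stats::rnorm(p_covs, sd = 0.5)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (sum(y) >= 3 && sum(1 - y) >= 3) break
  }
  df <- data.frame(y = y, X)
  names(df) <- c("y", paste0("x", seq_len(p_covs)))
  subject_data(df, outcome = "y", covariates = paste0("x", seq_len(p_covs)))
}
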