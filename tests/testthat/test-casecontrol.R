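make_cohort <- function(N, n_cases, seed = 1) {
  set.seed(seed)
  y <- c(rep(1, n_cases), rep(0, N - n_cases))
  subject_data(data.frame(y = y, x = rnorm(N), z = rbinom(N, 1, 0.4)),
               outcome = "y", covariates = c("x", "z"))
}

test_that("weights_from_counts implements available / sampled", {
  expect_equal(unname(weights_from_counts(900, 100)), 9.0)
  expect_equal(unname(weights_from_counts(80, 80)), 1.0)
  w <- weights_from_counts(c(a = 800, b = 100), c(a = 80, b = 50))
  expect_equal(w, c(a = 10.0, b = 2.0))
  expect_error(weights_from_counts(c(a = 10), c(a = 11)), "exceeds")
  expect_error(weights_from_counts(c(a = 10), c(a = 0)), "no controls")
})

test_that("simple random 1:1 sampling gives the stated sizes and weights", {
  cohort <- make_cohort(1000, 100)
  s <- sample_case_control(cohort, sampling_design(ratio = 1), seed = 5)
  expect_equal(nrow(s$df), 200L)
  expect_equal(sum(s$df$y), 100L)                  # all cases kept
  expect_true(all(s$df$.weight[s$df$y == 1] == 1))
  expect_true(all(s$df$.weight[s$df$y == 0] == 900 / 100))
  # reproducible for a fixed seed
  s2 <- sample_case_control(cohort, sampling_design(ratio = 1), seed = 5)
  expect_identical(s$df, s2$df)
})

test_that("matched sampling draws m x cases per stratum with stratum weights", {
  set.seed(31)
  N <- 2000
  z <- rbinom(N, 1, 0.35)
  y <- rbinom(N, 1, ifelse(z == 1, 0.12, 0.05))
  cohort <- subject_data(data.frame(y = y, x = rnorm(N), z = z),
                         outcome = "y", covariates = c("x", "z"))
  s <- sample_case_control(cohort, sampling_design(2, match_on = "z"),
                           seed = 6)
  bk <- attr(s, "sampling")
  for (zz in c(0, 1)) {
    cases_z <- sum(y == 1 & z == zz)
    ctrl_sampled <- sum(s$df$y == 0 & s$df$z == zz)
    expect_equal(ctrl_sampled, 2L * cases_z)
    avail <- sum(y == 0 & z == zz)
    expect_true(all(abs(s$df$.weight[s$df$y == 0 & s$df$z == zz] -
                          avail / ctrl_sampled) < 1e-12))
    row <- bk[bk$stratum == as.character(zz), ]
    expect_equal(row$available, avail)
    expect_equal(row$sampled, ctrl_sampled)
  }
  expect_true(all(s$df$.weight >= 1))
})

test_that("Horvitz-Thompson: weights reconstruct the cohort size", {
  cohort <- make_cohort(1000, 100)
  s <- sample_case_control(cohort, sampling_design(1), seed = 7)
  expect_equal(sum(s$df$.weight), 1000)   # 100 x 1 + 100 x 9
})

test_that("insufficient controls are all taken with weight 1 and a warning", {
  cohort <- make_cohort(120, 100)         # only 20 non-cases
  expect_warning(
    s <- sample_case_control(cohort, sampling_design(1), seed = 8),
    "taking all")
  expect_equal(nrow(s$df), 120L)
  expect_true(all(s$df$.weight == 1))
})

test_that("sampling fraction 1 reproduces the cohort fit exactly", {
  set.seed(32)
  N <- 600
  x <- rnorm(N); z <- rbinom(N, 1, 0.4)
  y <- rbinom(N, 1, exp(-2 + 0.4 * x + 0.3 * z))
  cohort <- subject_data(data.frame(y = y, x = x, z = z),
                         outcome = "y", covariates = c("x", "z"))
  # ratio large enough to exhaust every non-case
  suppressWarnings(
    s <- sample_case_control(cohort, sampling_design(50), seed = 9))
  expect_equal(nrow(s$df), N)
  expect_true(all(s$df$.weight == 1))
  f_cohort <- doubling_rr(cohort)
  f_cc <- doubling_rr(s)
  expect_equal(coef(f_cc), coef(f_cohort), tolerance = 1e-10)
  expect_equal(f_cc$robust_vcov, f_cohort$robust_vcov, tolerance = 1e-10)
})

test_that("weighted case-control doubling recovers the cohort lnRR", {
  # scaled down from the full 2000-replicate consistency sweep (budget):
  # two representative scenarios at R = 400; |bias| < 0.02 as stated
  for (cfg in list(list(p = 0.3, rr = 1.5, design = "random"),
                   list(p = 0.4, rr = 2, design = "matched"))) {
    sc <- rr_scenario(cfg$p, cfg$rr, cfg$design, replicates = 400,
                      seed = 77)
    res <- run_scenario(sc, "expanded_logistic")
    expect_lt(abs(res$bias), 0.02)
  }
})

test_that("design validation errors", {
  expect_error(sampling_design(0), "positive integer")
  expect_error(sampling_design(1.5), "positive integer")
  cohort <- make_cohort(100, 10)
  expect_error(
    sample_case_control(cohort, sampling_design(1, match_on = "nope")),
    "not found")
  no_cases <- subject_data(data.frame(y = rep(0, 10), x = 1:10), "y", "x")
  expect_error(sample_case_control(no_cases, sampling_design(1)),
               "no cases")
})
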