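## Comparison estimators: naive logistic OR, log-binomial RR (with a
## constrained fallback for the well-known IRLS convergence failures), and
## Poisson RR with a cluster-robust sandwich SE. All solvers are
## self-contained (no stats::glm), so glm can act as a test oracle.

new_alt_fit <- function(method, coefficients, vcov, converged,
                        iterations, loglik, boundary = FALSE, level = 0.95) {
  b <- coefficients
  se <- sqrt(diag(vcov))
  z <- stats::qnorm((1 + level) / 2)
  structure(
    list(method = method, coefficients = b, vcov = vcov,
         converged = converged, iterations = iterations, loglik = loglik,
         boundary = boundary, level = level,
         ci = data.frame(term = names(b), estimate_log = unname(b),
                         RR = exp(unname(b)), SE = unname(se),
                         CI_low = exp(unname(b - z * se)),
                         CI_high = exp(unname(b + z * se)),
                         row.names = NULL)),
    class = "alt_fit")
}

#' @export
print.alt_fit <- function(x, digits = 4, ...) {
  lab <- c(naive_logistic = "Naive logistic regression (odds ratios)",
           log_binomial = "Log-binomial regression (risk ratios)",
           poisson_robust = "Poisson regression with robust SE (risk ratios)")
  cat(lab[[x$method]], "\n")
  if (isTRUE(x$boundary))
    cat("NOTE: solution on the boundary of the parameter space",
        "(some fitted probabilities reach 1); Wald SEs are dubious here\n")
  tab <- x$ci[, c("RR", "SE", "CI_low", "CI_high")]
  rownames(tab) <- x$ci$term
  print(signif(tab, digits))
  invisible(x)
}

#' @export
coef.alt_fit <- function(object, ...) object$coefficients

#' @export
vcov.alt_fit <- function(object, ...) object$vcov

#' Naive logistic regression on the unexpanded data
#'
#' Ordinary (weighted) logistic MLE of the outcome on the covariates; the
#' exponentiated coefficients are odds ratios, often reported as an
#' approximation to the RR for rare outcomes.
#'
#' @param data a \code{\link{subject_data}}.
#' @param level confidence level.
#' @return an \code{alt_fit} with the naive (inverse-Hessian) covariance.
#' @export
fit_naive_logistic <- function(data, level = 0.95) {
  stopifnot(inherits(data, "subject_data"))
  X <- design_matrix(data)
  df <- data$df
  fit <- logit_irls(X, df[[data$outcome]], df$.weight)
  V <- solve(fit$information)
  dimnames(V) <- list(colnames(X), colnames(X))
  new_alt_fit("naive_logistic", fit$coefficients, V, fit$converged,
              fit$iterations, fit$loglik, level = level)
}

# log-binomial IRLS with expected information; steps that leave the
# admissible region (any linear predictor >= 0) are halved
logbin_irls <- function(X, y, w, max_iter = 100L,
                        score_tol = 1e-8, coef_tol = 1e-10) {
  beta <- numeric(ncol(X))
  ybar <- stats::weighted.mean(y, w)
  if (ybar <= 0 || ybar >= 1) stop("outcome is constant")
  beta[1] <- log(ybar)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- exp(eta)
    score <- drop(crossprod(X, w * (y - (1 - y) * p / (1 - p))))
    info <- crossprod(X, X * (w * p / (1 - p)))
    delta <- solve(info, score)
    step <- 1
    repeat {
      cand <- beta + step * delta
      if (max(X %*% cand) < 0) break
      step <- step / 2
      if (step < 1e-10)
        stop("log-binomial IRLS step cannot stay inside the parameter space")
    }
    beta <- beta + step * delta
    if (max(abs(score)) < score_tol && max(abs(step * delta)) < coef_tol)
      return(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                  iterations = it))
  }
  stop("log-binomial IRLS failed to converge in ", max_iter, " iterations")
}

# constrained fallback: maximize the binomial log-likelihood with log link
# over { theta : max_i x_i' theta <= 0 } (fitted probabilities <= 1) via
# constrOptim with the linear constraint -X theta >= 0
logbin_constrained <- function(X, y, w) {
  nll <- function(th) {
    eta <- drop(X %*% th)
    if (max(eta) >= 0) return(Inf)
    -sum(w * (y * eta + (1 - y) * log1p(-exp(eta))))
  }
  grad <- function(th) {
    eta <- drop(X %*% th)
    p <- exp(pmin(eta, -1e-12))
    -drop(crossprod(X, w * (y - (1 - y) * p / (1 - p))))
  }
  ybar <- stats::weighted.mean(y, w)
  th0 <- c(log(ybar) - 0.5, numeric(ncol(X) - 1L))
  o <- stats::constrOptim(th0, nll, grad, ui = -X, ci = rep(0, nrow(X)),
                          method = "BFGS", outer.iterations = 200,
                          outer.eps = 1e-10)
  if (o$convergence != 0)
    stop("constrained log-binomial optimization failed (code ",
         o$convergence, ")")
  list(coefficients = stats::setNames(o$par, colnames(X)),
       iterations = o$outer.iterations,
       boundary = max(X %*% o$par) > -1e-6)
}

#' Log-binomial regression (direct relative-risk model)
#'
#' Maximizes the binomial log-likelihood with log link, whose exponentiated
#' coefficients are adjusted risk ratios. The primary path is IRLS with
#' step-halving to keep fitted probabilities below 1; when IRLS fails (the
#' classic convergence problem of this model) the likelihood is maximized
#' directly under the linear constraints max_i x_i'theta <= 0, and the
#' \code{boundary} flag marks solutions attaining the constraint, where Wald
#' SEs are unreliable.
#'
#' @inheritParams fit_naive_logistic
#' @return an \code{alt_fit}; \code{vcov} is the inverse expected
#'   information at the optimum (a boundary solution triggers a warning).
#' @export
fit_log_binomial <- function(data, level = 0.95) {
  stopifnot(inherits(data, "subject_data"))
  X <- design_matrix(data)
  df <- data$df
  y <- df[[data$outcome]]
  w <- df$.weight
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]],
               collapse = ", "))

  irls_err <- NULL
  fit <- tryCatch(logbin_irls(X, y, w), error = function(e) {
    irls_err <<- conditionMessage(e); NULL
  })
  boundary <- FALSE
  if (is.null(fit)) {
    fit <- tryCatch(logbin_constrained(X, y, w), error = function(e)
      stop("log-binomial fit failed on both paths; IRLS: ", irls_err,
           "; constrained: ", conditionMessage(e)))
    boundary <- fit$boundary
  }
  eta <- pmin(drop(X %*% fit$coefficients), -1e-10)
  p <- exp(eta)
  info <- crossprod(X, X * (w * p / (1 - p)))
  V <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(V) <- list(colnames(X), colnames(X))
  if (boundary)
    warning("log-binomial solution lies on the boundary of the parameter ",
            "space; Wald standard errors are unreliable")
  ll <- sum(w * (y * eta + (1 - y) * log1p(-p)))
  new_alt_fit("log_binomial", fit$coefficients, V, TRUE, fit$iterations,
              ll, boundary = boundary, level = level)
}

#' Poisson regression with cluster-robust SE (modified Poisson RR)
#'
#' Log-link Poisson pseudo-MLE of the binary outcome; the exponentiated
#' coefficients estimate risk ratios. The covariance is the sandwich with
#' one cluster per subject, with sampling weights entering the
#' pseudo-likelihood once and the meat squared, mirroring the weighted
#' expanded-data logistic sandwich.
#'
#' @inheritParams fit_naive_logistic
#' @return an \code{alt_fit} with the robust covariance.
#' @export
fit_poisson_robust <- function(data, level = 0.95) {
  stopifnot(inherits(data, "subject_data"))
  X <- design_matrix(data)
  df <- data$df
  y <- df[[data$outcome]]
  w <- df$.weight
  beta <- numeric(ncol(X))
  beta[1] <- log(max(stats::weighted.mean(y, w), 1e-8))
  conv <- FALSE
  for (it in seq_len(100L)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, w * (y - mu)))
    info <- crossprod(X, X * (w * mu))
    delta <- solve(info, score)
    beta <- beta + delta
    if (max(abs(score)) < 1e-8 && max(abs(delta)) < 1e-10) { conv <- TRUE; break }
  }
  if (!conv) stop("Poisson IRLS failed to converge in 100 iterations")
  mu <- exp(drop(X %*% beta))
  info <- crossprod(X, X * (w * mu))
  bread <- solve(info)
  meat <- crossprod((w * (y - mu)) * X)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- sum(w * (y * log(mu) - mu - lgamma(y + 1)))
  new_alt_fit("poisson_robust", stats::setNames(beta, colnames(X)), V,
              TRUE, it, ll, level = level)
}
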