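## Core estimator: (weighted) logistic regression of the expanded data, with
## the robust sandwich covariance clustered on the original subject. The IRLS
## solver is deliberately self-contained so that stats::glm can serve as an
## independent oracle in the test suite.

# Weighted logistic IRLS on a prepared design matrix.
# Convergence: max |score| < score_tol AND max |delta coef| < coef_tol.
logit_irls <- function(X, y, w, max_iter = 100L,
                       score_tol = 1e-8, coef_tol = 1e-10) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  if (all(y == y[1]))
    stop("outcome is constant (all ", y[1], "); model cannot be fitted")

  loglik <- function(b) {
    eta <- drop(X %*% b)
    # overflow-safe log(1 + e^eta)
    sum(w * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
  }
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(min(max(stats::weighted.mean(y, w), 1e-6), 1 - 1e-6))
  ll <- loglik(beta)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, w * (y - p)))
    info <- crossprod(X, X * (w * p * (1 - p)))
    delta <- tryCatch(solve(info, score), error = function(e)
      stop("information matrix singular at iteration ", it,
           " (possible separation)"))
    # Newton with step-halving: a full step can overshoot badly when the
    # starting slope is far off; halve until the likelihood does not drop
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_cand <- loglik(cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop("logistic IRLS step-halving failed at iteration ", it,
             " (possible separation)")
    }
    beta <- cand
    ll <- ll_cand
    delta <- step * delta
    trace <- c(trace, max(abs(score)))
    if (max(abs(score)) < score_tol && max(abs(delta)) < coef_tol) {
      eta <- drop(X %*% beta)
      p <- stats::plogis(eta)
      info <- crossprod(X, X * (w * p * (1 - p)))
      ll <- sum(w * (y * log(p) + (1 - y) * log1p(-p)))
      return(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                  fitted = p, information = info, loglik = ll,
                  iterations = it, converged = TRUE))
    }
  }
  stop("logistic IRLS failed to converge in ", max_iter,
       " iterations (possible separation); |score| trace: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = " -> "))
}

#' Fit the expanded-data logistic regression (doubling-of-cases RR)
#'
#' Maximizes the (weighted) logistic log pseudo-likelihood of the expanded
#' data. The exponentiated covariate coefficients estimate adjusted risk
#' ratios of the source data. The returned fit carries both the naive
#' covariance (inverse Hessian of the pseudo-likelihood, valid only for rare
#' outcomes) and the robust sandwich covariance clustered on the original
#' subject, which corrects for the artificial case duplication and, in
#' weighted fits, for the sampling weights.
#'
#' @param expanded an \code{\link{expand_cases}} result.
#' @param level confidence level for the reported Wald intervals.
#' @return An object of class \code{rr_fit} with elements
#'   \code{coefficients} (log scale), \code{naive_vcov}, \code{robust_vcov},
#'   \code{residuals} (per original subject, named by id), \code{converged},
#'   \code{iterations}, \code{loglik}, \code{level}, \code{ci} (see
#'   \code{\link{wald_ci}}).
#' @export
fit_expanded_logistic <- function(expanded, level = 0.95) {
  stopifnot(inherits(expanded, "expanded_data"))
  df <- expanded$df
  X <- design_matrix(expanded)
  y <- df[[expanded$outcome]]
  w <- df$.weight
  if (!any(y == 1) || !any(y == 0))
    stop("expanded data need at least one case and one non-case record")

  fit <- logit_irls(X, y, w)
  naive_vcov <- solve(fit$information)
  dimnames(naive_vcov) <- list(colnames(X), colnames(X))

  obj <- structure(
    list(coefficients = fit$coefficients,
         naive_vcov = naive_vcov,
         robust_vcov = NULL, residuals = NULL,
         fitted = fit$fitted,
         converged = fit$converged, iterations = fit$iterations,
         loglik = fit$loglik, weighted = !all(w == 1),
         level = level, method = "expanded_logistic"),
    class = "rr_fit")
  obj$robust_vcov <- robust_covariance(obj, expanded)
  obj$residuals <- attr(obj$robust_vcov, "residuals")
  attr(obj$robust_vcov, "residuals") <- NULL
  obj$ci <- wald_ci(obj, level = level)
  obj
}

#' Robust sandwich covariance for an expanded-data logistic fit
#'
#' Computes V = H1^-1 H2 H1^-1 where H1 is the Hessian of the (weighted)
#' pseudo log-likelihood (so H1^-1 is the naive covariance) and H2 sums, over
#' ORIGINAL subjects, the outer products of per-subject score contributions
#' w_i r*_i x_i. A doubled case's two expanded records share covariates and
#' weight, so its residual r*_i is the sum of the two record-level errors
#' (1 - p*_i) + (- p*_i); a non-case contributes - p*_i. Weights enter the
#' meat squared. No finite-sample degrees-of-freedom correction is applied.
#'
#' @param fit an \code{rr_fit} (converged on \code{expanded}).
#' @param expanded the \code{expanded_data} the fit was computed from.
#' @return the robust covariance matrix, with the per-subject residuals
#'   r*_i attached as attribute \code{"residuals"}.
#' @export
robust_covariance <- function(fit, expanded) {
  stopifnot(inherits(fit, "rr_fit"), inherits(expanded, "expanded_data"))
  df <- expanded$df
  if (is.null(df$.id)) stop("expanded data lack subject ids")
  X <- design_matrix(expanded)
  y <- df[[expanded$outcome]]
  p <- stats::plogis(drop(X %*% fit$coefficients))
  if (length(p) != length(fit$fitted) ||
      max(abs(p - fit$fitted)) > 1e-8)
    stop("fit does not match the supplied expanded data")

  # per-subject score: cluster record-level scores w (y - p) x on subject id
  id <- df$.id
  scores <- rowsum(df$.weight * (y - p) * X, group = id, reorder = FALSE)
  meat <- crossprod(scores)
  bread <- fit$naive_vcov
  V <- bread %*% meat %*% bread
  dimnames(V) <- dimnames(bread)
  # per-subject residuals r*_i (weight excluded), for diagnostics
  rstar <- rowsum(y - p, group = id, reorder = FALSE)
  attr(V, "residuals") <- stats::setNames(drop(rstar), rownames(rstar))
  V
}

#' Wald confidence intervals on the risk-ratio scale
#'
#' Intervals are Wald on the log scale using the robust SE, then
#' exponentiated: exp(coef +/- z * SE).
#'
#' @param fit an \code{rr_fit}.
#' @param level confidence level in (0, 1).
#' @return data.frame with columns \code{term}, \code{estimate_log},
#'   \code{RR}, \code{naive_SE}, \code{robust_SE}, \code{CI_low},
#'   \code{CI_high} (RR scale), \code{CI_low_log}, \code{CI_high_log}.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rr_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  if (is.null(fit$robust_vcov)) stop("robust covariance not available")
  b <- fit$coefficients
  rse <- sqrt(diag(fit$robust_vcov))
  nse <- sqrt(diag(fit$naive_vcov))
  z <- stats::qnorm((1 + level) / 2)
  data.frame(term = names(b),
             estimate_log = unname(b),
             RR = exp(unname(b)),
             naive_SE = unname(nse),
             robust_SE = unname(rse),
             CI_low = exp(unname(b - z * rse)),
             CI_high = exp(unname(b + z * rse)),
             CI_low_log = unname(b - z * rse),
             CI_high_log = unname(b + z * rse),
             row.names = NULL)
}

#' @export
print.rr_fit <- function(x, digits = 4, ...) {
  cat("Expanded-data logistic regression",
      if (isTRUE(x$weighted)) "(sampling-weighted)", "\n")
  ci <- x$ci
  tab <- data.frame(RR = ci$RR, robust_SE = ci$robust_SE,
                    CI_low = ci$CI_low, CI_high = ci$CI_high,
                    row.names = ci$term)
  print(signif(tab, digits))
  cat(sprintf("converged in %d iterations; log pseudo-likelihood %.4f\n",
              x$iterations, x$loglik))
  invisible(x)
}

#' @export
coef.rr_fit <- function(object, ...) object$coefficients

#' @export
vcov.rr_fit <- function(object, robust = TRUE, ...)
  if (robust) object$robust_vcov else object$naive_vcov

#' @export
confint.rr_fit <- function(object, parm, level = 0.95, ...) {
  ci <- wald_ci(object, level = level)
  m <- as.matrix(ci[, c("CI_low", "CI_high")])
  rownames(m) <- ci$term
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Doubling-of-cases risk-ratio estimate in one call
#'
#' Convenience wrapper: expands the cases, fits the (weighted) logistic
#' regression, and attaches robust Wald intervals.
#'
#' @inheritParams expand_cases
#' @inheritParams fit_expanded_logistic
#' @return an \code{rr_fit}.
#' @export
doubling_rr <- function(data, level = 0.95) {
  fit_expanded_logistic(expand_cases(data), level = level)
}
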