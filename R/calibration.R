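#' Fit the empirical null distribution from negative-control estimates
#'
#' Negative-control outcomes are assumed causally unrelated to
#' vaccination, so the spread of their estimates around a rate ratio of 1
#' measures residual systematic error. The null models each
#' negative-control log-RR \eqn{\hat\theta_i} as
#' \eqn{N(\mu, \sigma^2 + \hat\tau_i^2)} and fits \eqn{(\mu, \sigma)} by
#' maximum likelihood over \eqn{(\mu, \log\sigma)} (sigma floored at
#' 1e-8). Deterministic.
#'
#' @param theta numeric vector of negative-control log rate ratios.
#' @param tau numeric vector of their standard errors (same length).
#'   Pairs with missing values (e.g. zero-event negative controls) are
#'   dropped before fitting.
#' @param min_controls minimum usable estimates required (default 5);
#'   fewer precludes calibration and raises a classed error.
#' @return an object of class \code{null_distribution}: \code{mu},
#'   \code{sigma}, \code{m}.
#' @export
fit_null <- function(theta, tau, min_controls = 5L) {
  ok <- is.finite(theta) & is.finite(tau) & tau > 0
  theta <- theta[ok]; tau <- tau[ok]
  m <- length(theta)
  if (m < min_controls)
    stopf("too few negative control outcomes to fit an empirical null (%d usable, need >= %d)",
          m, min_controls, class = "vaxsafety_calibration_error")
  negll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    s <- sqrt(sigma^2 + tau^2)
    -sum(stats::dnorm(theta, mu, s, log = TRUE))
  }
  start <- c(mean(theta), log(max(stats::sd(theta), 1e-4)))
  fit <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(mu = fit$par[1],
                 sigma = max(exp(fit$par[2]), 1e-8),
                 m = m),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Empirical null: mu = %.4f, sigma = %.4f (from %d negative controls)\n",
              x$mu, x$sigma, x$m))
  invisible(x)
}

#' Calibrate an effect estimate against an empirical null
#'
#' Calibrated two-sided p-value:
#' \eqn{2(1 - \Phi(|\hat\theta - \mu| / \sqrt{\sigma^2 + \hat\tau^2}))};
#' calibrated CI:
#' \eqn{\exp(\hat\theta - \mu \pm 1.96\sqrt{\sigma^2 + \hat\tau^2})}.
#' With a (0, 0) null the calibrated quantities equal the uncalibrated
#' ones. Not-estimable inputs propagate their flag.
#'
#' @param estimate an [poisson_irr()]-style \code{effect_estimate} (or any
#'   list with \code{log_rr}, \code{se}, \code{estimable}).
#' @param null a [fit_null()] result.
#' @return an object of class \code{calibrated_estimate}:
#'   \code{uncalibrated}, \code{rr}, \code{ci95_low}, \code{ci95_high},
#'   \code{p}, \code{null}, \code{estimable}.
#' @export
calibrate <- function(estimate, null) {
  if (!isTRUE(estimate$estimable)) {
    out <- list(uncalibrated = estimate, rr = NA_real_,
                ci95_low = NA_real_, ci95_high = NA_real_, p = NA_real_,
                null = null, estimable = FALSE)
    class(out) <- "calibrated_estimate"
    return(out)
  }
  s <- sqrt(null$sigma^2 + estimate$se^2)
  z <- stats::qnorm(0.975)
  centred <- estimate$log_rr - null$mu
  out <- list(uncalibrated = estimate,
              rr = exp(centred),
              ci95_low = exp(centred - z * s),
              ci95_high = exp(centred + z * s),
              p = 2 * stats::pnorm(-abs(centred) / s),
              null = null,
              estimable = TRUE)
  class(out) <- "calibrated_estimate"
  out
}

#' @export
print.calibrated_estimate <- function(x, ...) {
  if (!x$estimable) cat("calibrated estimate: not estimable\n")
  else cat(sprintf("calibrated IRR %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
                   x$rr, x$ci95_low, x$ci95_high, x$p))
  invisible(x)
}

#' Negative-control residual-bias diagnostic
#'
#' The fraction of estimable negative controls whose uncalibrated 95% CI
#' excludes 1. The analysis passes when the fraction is strictly below
#' the threshold; on failure only calibrated estimates should be relied
#' on downstream.
#'
#' @param estimates list of \code{effect_estimate} objects (negative
#'   controls).
#' @param threshold strict failure bound on the significant fraction
#'   (default 0.20).
#' @return list: \code{fraction}, \code{n_significant}, \code{n_estimable},
#'   \code{pass}, \code{evaluable}.
#' @export
nc_diagnostic <- function(estimates, threshold = 0.20) {
  est <- Filter(function(e) isTRUE(e$estimable), estimates)
  if (!length(est))
    return(list(fraction = NA_real_, n_significant = 0L,
                n_estimable = 0L, pass = NA, evaluable = FALSE))
  sig <- vapply(est, function(e) e$ci95_low > 1 || e$ci95_high < 1,
                logical(1))
  frac <- mean(sig)
  list(fraction = frac, n_significant = sum(sig),
       n_estimable = length(est), pass = frac < threshold,
       evaluable = TRUE)
}
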