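#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments pooling of per-database log rate ratios: with
#' fixed-effect weights \eqn{w_i = 1/\hat\tau_i^2},
#' \eqn{Q = \sum w_i (\hat\theta_i - \bar\theta_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))}, and
#' random-effects weights \eqn{w_i^* = 1/(\hat\tau_i^2 + \tau^2)}.
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100} (reported as 0 when
#' \eqn{k = 1} or \eqn{Q = 0}).
#'
#' @param theta per-database log rate ratios.
#' @param tau per-database standard errors.
#' @param labels optional database labels.
#' @param i2_warn_threshold emit a heterogeneity warning above this I^2
#'   percentage (default 60).
#' @return an object of class \code{meta_estimate}: \code{log_rr},
#'   \code{se}, \code{rr}, \code{ci95_low}, \code{ci95_high}, \code{p},
#'   \code{q}, \code{tau2}, \code{i2}, \code{k}, \code{labels},
#'   \code{estimable}.
#' @export
dl_meta <- function(theta, tau, labels = NULL, i2_warn_threshold = 60) {
  ok <- is.finite(theta) & is.finite(tau) & tau > 0
  theta <- theta[ok]; tau <- tau[ok]
  if (!is.null(labels)) labels <- labels[ok]
  k <- length(theta)
  if (k == 0)
    stopf("no estimable inputs for meta-analysis",
          class = "vaxsafety_input_error")
  w <- 1 / tau^2
  theta_fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_fe)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
          else 0
  ws <- 1 / (tau^2 + tau2)
  pooled <- sum(ws * theta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  z <- stats::qnorm(0.975)
  out <- structure(list(log_rr = pooled, se = se, rr = exp(pooled),
                        ci95_low = exp(pooled - z * se),
                        ci95_high = exp(pooled + z * se),
                        p = 2 * stats::pnorm(-abs(pooled) / se),
                        q = q, tau2 = tau2, i2 = i2, k = k,
                        labels = labels, estimable = TRUE),
                   class = "meta_estimate")
  if (is.finite(i2) && i2 > i2_warn_threshold)
    warning(sprintf("high between-database heterogeneity (I2 = %.0f%%); pooled estimate may be unreliable",
                    i2), call. = FALSE)
  out
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("Random-effects pooled IRR %.3f (95%% CI %.3f to %.3f), k = %d\n",
              x$rr, x$ci95_low, x$ci95_high, x$k))
  cat(sprintf("  Q = %.3f, tau2 = %.4f, I2 = %.1f%%\n", x$q, x$tau2, x$i2))
  invisible(x)
}

#' Meta-analysis with pooled empirical calibration
#'
#' Each negative control is meta-analysed across databases with
#' [dl_meta()]; an empirical null is fitted to the pooled
#' negative-control estimates; the pooled outcome estimate is then
#' calibrated against that null. With a single database this reduces to
#' the database-level calibration. When too few pooled negative controls
#' are usable, the uncalibrated pooled estimate is still returned with a
#' \code{calibration_available = FALSE} flag.
#'
#' @param outcome_estimates list of per-database \code{effect_estimate}
#'   objects for the outcome of interest.
#' @param nc_estimates list over negative controls; each element a list of
#'   per-database \code{effect_estimate} objects for that control.
#' @param labels optional database labels (aligned with
#'   \code{outcome_estimates}).
#' @param min_controls minimum pooled negative controls for the null fit.
#' @return list: \code{pooled} ([dl_meta()] result), \code{calibrated}
#'   ([calibrate()] result or NULL), \code{null}, \code{pooled_ncs}
#'   (data.frame of pooled NC estimates), \code{calibration_available}.
#' @export
pooled_calibration <- function(outcome_estimates, nc_estimates,
                               labels = NULL, min_controls = 5L) {
  est <- Filter(function(e) isTRUE(e$estimable), outcome_estimates)
  pooled <- dl_meta(vapply(est, `[[`, 0, "log_rr"),
                    vapply(est, `[[`, 0, "se"), labels = labels)
  nc_pooled <- lapply(nc_estimates, function(per_db) {
    usable <- Filter(function(e) isTRUE(e$estimable), per_db)
    if (!length(usable)) return(NULL)
    m <- suppressWarnings(dl_meta(vapply(usable, `[[`, 0, "log_rr"),
                                  vapply(usable, `[[`, 0, "se")))
    c(theta = m$log_rr, tau = m$se)
  })
  nc_pooled <- do.call(rbind, Filter(Negate(is.null), nc_pooled))
  null <- tryCatch(
    fit_null(nc_pooled[, "theta"], nc_pooled[, "tau"],
             min_controls = min_controls),
    error = function(e) NULL)
  if (is.null(null)) {
    return(list(pooled = pooled, calibrated = NULL, null = NULL,
                pooled_ncs = nc_pooled, calibration_available = FALSE))
  }
  list(pooled = pooled,
       calibrated = calibrate(pooled, null),
       null = null,
       pooled_ncs = nc_pooled,
       calibration_available = TRUE)
}

#' Which databases contribute to the meta-analysis
#'
#' A database/comparison result enters the meta-analysis iff it passed
#' the covariate-balance diagnostic; the power and negative-control
#' diagnostics only suppress database-specific reporting, they do not
#' exclude from pooling.
#'
#' @param results list of per-database result entries, each with
#'   \code{database} and \code{balance_pass}.
#' @return character vector of contributing database names.
#' @export
inclusion_rule <- function(results) {
  keep <- vapply(results, function(r) isTRUE(r$balance_pass), logical(1))
  vapply(results[keep], `[[`, "", "database")
}
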