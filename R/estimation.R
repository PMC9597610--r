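#' Person-time at risk
#'
#' Per entry, time at risk runs from the index day to the first outcome
#' event (if any) or the follow-up end, in years (365.25 days/year).
#'
#' @param cohort cohort data.frame (\code{index_day},
#'   \code{follow_up_end_day}).
#' @param event_days integer vector aligned with \code{cohort}: first
#'   in-window event day per entry, \code{NA} when none.
#' @return numeric vector of person-years, one per entry.
#' @export
person_time <- function(cohort, event_days = rep(NA_integer_, nrow(cohort))) {
  end <- ifelse(is.na(event_days), cohort$follow_up_end_day,
                pmin(event_days, cohort$follow_up_end_day))
  days <- end - cohort$index_day
  if (any(days < 0))
    stopf("negative at-risk interval (event before index?)",
          class = "vaxsafety_input_error")
  days / 365.25
}

#' Incidence rate per 1000 person-years with exact Poisson CI
#'
#' Rate = events / person-years x 1000. The 95% interval uses the exact
#' (chi-square) bounds on the Poisson count divided by person-time:
#' \eqn{[\chi^2_{0.025, 2x}/2, \chi^2_{0.975, 2(x+1)}/2] / T}.
#'
#' @param events non-negative event count.
#' @param person_years person-time at risk (> 0), in years.
#' @param conf confidence level (default 0.95).
#' @return an object of class \code{rate_summary}: \code{events},
#'   \code{person_years}, \code{rate_per_1000py}, \code{ci95_low},
#'   \code{ci95_high}.
#' @export
incidence_rate <- function(events, person_years, conf = 0.95) {
  if (!is.finite(person_years) || person_years <= 0)
    stopf("person_years must be > 0", class = "vaxsafety_input_error")
  if (events < 0)
    stopf("events must be >= 0", class = "vaxsafety_input_error")
  a <- (1 - conf) / 2
  lo <- if (events == 0) 0 else stats::qchisq(a, 2 * events) / 2
  hi <- stats::qchisq(1 - a, 2 * (events + 1)) / 2
  structure(list(events = events,
                 person_years = person_years,
                 rate_per_1000py = events / person_years * 1000,
                 ci95_low = lo / person_years * 1000,
                 ci95_high = hi / person_years * 1000),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%d events / %.1f person-years: %.2f (%.2f to %.2f) per 1000 py\n",
              x$events, x$person_years, x$rate_per_1000py, x$ci95_low,
              x$ci95_high))
  invisible(x)
}

#' Poisson incidence rate ratio
#'
#' Closed-form Poisson IRR: \eqn{\hat\theta = \log[(x_t/T_t)/(x_c/T_c)]},
#' \eqn{\hat\tau = \sqrt{1/x_t + 1/x_c}}, with Wald CI and two-sided
#' p-value. Identical (to numerical precision) to a Poisson regression of
#' counts on an arm indicator with a log person-time offset. A zero event
#' count in either arm yields a not-estimable result (no continuity
#' correction).
#'
#' @param events_target,events_comparator event counts.
#' @param py_target,py_comparator person-years (> 0).
#' @return an object of class \code{effect_estimate}: \code{log_rr}
#'   (\eqn{\hat\theta}), \code{se} (\eqn{\hat\tau}), \code{rr},
#'   \code{ci95_low}, \code{ci95_high}, \code{p}, \code{estimable}, and
#'   the four cells.
#' @export
poisson_irr <- function(events_target, py_target,
                        events_comparator, py_comparator) {
  if (py_target <= 0 || py_comparator <= 0)
    stopf("person-time must be > 0 in both arms",
          class = "vaxsafety_input_error")
  cells <- list(events_target = events_target, py_target = py_target,
                events_comparator = events_comparator,
                py_comparator = py_comparator)
  if (events_target == 0 || events_comparator == 0) {
    est <- c(list(log_rr = NA_real_, se = NA_real_, rr = NA_real_,
                  ci95_low = NA_real_, ci95_high = NA_real_, p = NA_real_,
                  estimable = FALSE), cells)
  } else {
    theta <- log((events_target / py_target) /
                   (events_comparator / py_comparator))
    tau <- sqrt(1 / events_target + 1 / events_comparator)
    z <- stats::qnorm(0.975)
    est <- c(list(log_rr = theta, se = tau, rr = exp(theta),
                  ci95_low = exp(theta - z * tau),
                  ci95_high = exp(theta + z * tau),
                  p = 2 * stats::pnorm(-abs(theta) / tau),
                  estimable = TRUE), cells)
  }
  class(est) <- "effect_estimate"
  est
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat("IRR not estimable (zero events in one arm)\n")
  } else {
    cat(sprintf("IRR %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
                x$rr, x$ci95_low, x$ci95_high, x$p))
    cat(sprintf("  cells: %d events / %.1f py vs %d events / %.1f py\n",
                x$events_target, x$py_target, x$events_comparator,
                x$py_comparator))
  }
  invisible(x)
}

#' Incidence rate difference per 1000 person-years
#'
#' \eqn{\Delta = rate_t - rate_c} with Wald standard error
#' \eqn{\sqrt{x_t/T_t^2 + x_c/T_c^2} \times 1000}.
#'
#' @param rate_target,rate_comparator [incidence_rate()] summaries.
#' @return list: \code{ird_per_1000py}, \code{se}, \code{ci95_low},
#'   \code{ci95_high}, \code{zero_width} (TRUE when both arms had zero
#'   events, in which case the interval is degenerate at 0).
#' @export
rate_difference <- function(rate_target, rate_comparator) {
  d <- rate_target$rate_per_1000py - rate_comparator$rate_per_1000py
  se <- sqrt(rate_target$events / rate_target$person_years^2 +
               rate_comparator$events / rate_comparator$person_years^2) * 1000
  z <- stats::qnorm(0.975)
  list(ird_per_1000py = d, se = se,
       ci95_low = d - z * se, ci95_high = d + z * se,
       zero_width = rate_target$events == 0 &&
         rate_comparator$events == 0)
}

#' 28-day absolute risk difference per 100 000 vaccinated
#'
#' Converts each arm's rate to a cumulative risk over the risk window
#' (\eqn{risk = 1 - \exp(-(rate/1000) \cdot w/365.25)}) and reports the
#' difference scaled to 100 000 vaccinees, with a delta-method Wald CI.
#'
#' @param rate_target,rate_comparator [incidence_rate()] summaries
#'   (per 1000 py).
#' @param window_days risk window length (default 28).
#' @return list: \code{ard_per_100k}, \code{se}, \code{ci95_low},
#'   \code{ci95_high}.
#' @export
absolute_risk_difference <- function(rate_target, rate_comparator,
                                     window_days = 28) {
  tyears <- window_days / 365.25
  risk <- function(rs) 1 - exp(-(rs$rate_per_1000py / 1000) * tyears)
  drisk_dlambda <- function(rs)
    tyears * exp(-(rs$rate_per_1000py / 1000) * tyears)
  var_lambda <- function(rs) rs$events / rs$person_years^2
  ard <- (risk(rate_target) - risk(rate_comparator)) * 1e5
  se <- sqrt(drisk_dlambda(rate_target)^2 * var_lambda(rate_target) +
               drisk_dlambda(rate_comparator)^2 *
                 var_lambda(rate_comparator)) * 1e5
  z <- stats::qnorm(0.975)
  list(ard_per_100k = ard, se = se,
       ci95_low = ard - z * se, ci95_high = ard + z * se)
}

#' Minimum detectable rate ratio
#'
#' The smallest rate ratio \eqn{\theta > 1} detectable at two-sided
#' \eqn{\alpha} with the given power, for the observed person-time split
#' and overall event rate. With baseline rate \eqn{r = x/(T_t + T_c)} and
#' expected counts \eqn{E_c = r T_c}, \eqn{E_t = \theta r T_t}, it is the
#' smallest \eqn{\theta} satisfying
#' \eqn{\log\theta \ge (z_{1-\alpha/2} + z_{power})\sqrt{1/E_t + 1/E_c}},
#' solved by bisection to 1e-6. Analyses with MDRR above
#' \code{gate_threshold} are considered underpowered.
#'
#' @param py_target,py_comparator person-years per arm (> 0).
#' @param total_events total observed events across arms.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @param gate_threshold pass iff MDRR <= this value (default 5).
#' @return an object of class \code{power_diagnostic}: \code{mdrr},
#'   \code{estimable}, \code{pass}.
#' @export
mdrr <- function(py_target, py_comparator, total_events,
                 alpha = 0.05, power = 0.80, gate_threshold = 5) {
  if (py_target <= 0 || py_comparator <= 0)
    stopf("person-time must be > 0 in both arms",
          class = "vaxsafety_input_error")
  if (total_events <= 0) {
    out <- list(mdrr = NA_real_, estimable = FALSE, pass = FALSE,
                alpha = alpha, power = power)
    class(out) <- "power_diagnostic"
    return(out)
  }
  r <- total_events / (py_target + py_comparator)
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  f <- function(theta) {
    et <- theta * r * py_target
    ec <- r * py_comparator
    log(theta) - zsum * sqrt(1 / et + 1 / ec)
  }
  lo <- 1; hi <- 2
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) < 0) {
    out <- list(mdrr = Inf, estimable = TRUE, pass = FALSE,
                alpha = alpha, power = power)
    class(out) <- "power_diagnostic"
    return(out)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  out <- list(mdrr = hi, estimable = TRUE, pass = hi <= gate_threshold,
              alpha = alpha, power = power)
  class(out) <- "power_diagnostic"
  out
}

#' @export
print.power_diagnostic <- function(x, ...) {
  if (!x$estimable) cat("MDRR not estimable (no events)\n")
  else cat(sprintf("MDRR = %.3f (alpha %.2f, power %.2f): %s\n", x$mdrr,
                   x$alpha, x$power,
                   if (x$pass) "sufficient power" else "underpowered"))
  invisible(x)
}

#' Full estimation chain for one two-arm comparison
#'
#' Rates, IRR, IRD, 28-day ARD and MDRR from the four cells.
#'
#' @param events_target,events_comparator event counts.
#' @param py_target,py_comparator person-years.
#' @param window_days risk-window length for the ARD (default 28).
#' @return list with \code{rate_target}, \code{rate_comparator},
#'   \code{irr}, \code{ird}, \code{ard}, \code{power}.
#' @export
estimate_comparison <- function(events_target, py_target,
                                events_comparator, py_comparator,
                                window_days = 28) {
  rt <- incidence_rate(events_target, py_target)
  rc <- incidence_rate(events_comparator, py_comparator)
  list(rate_target = rt,
       rate_comparator = rc,
       irr = poisson_irr(events_target, py_target, events_comparator,
                         py_comparator),
       ird = rate_difference(rt, rc),
       ard = absolute_risk_difference(rt, rc, window_days),
       power = mdrr(py_target, py_comparator,
                    events_target + events_comparator))
}

#' Age/sex-stratified effect estimates
#'
#' Runs the full estimation chain inside each stratum of 10-year age band
#' by sex. Strata that fail the power gate (MDRR above the threshold, or
#' no events) are suppressed, with the reason recorded.
#'
#' @param data data.frame with one row per matched person: \code{arm}
#'   (\code{target}/\code{comparator}), \code{days} at risk, \code{event}
#'   (0/1), \code{age}, \code{sex}.
#' @param gate_threshold MDRR pass bound (default 5).
#' @return data.frame with one row per stratum: the cells, \code{rr},
#'   \code{ci95_low}, \code{ci95_high}, \code{mdrr}, \code{reported},
#'   \code{reason}.
#' @export
stratified_estimates <- function(data, gate_threshold = 5) {
  band <- pmin(90L, (data$age %/% 10L) * 10L)
  strat <- interaction(band, data$sex, drop = TRUE, sep = "/")
  rows <- lapply(levels(strat), function(s) {
    d <- data[strat == s, ]
    res <- data.frame(stratum = s,
                      events_target = sum(d$event[d$arm == "target"]),
                      py_target = sum(d$days[d$arm == "target"]) / 365.25,
                      events_comparator = sum(d$event[d$arm == "comparator"]),
                      py_comparator = sum(d$days[d$arm == "comparator"]) /
                        365.25,
                      stringsAsFactors = FALSE)
    if (res$py_target <= 0 || res$py_comparator <= 0) {
      res$rr <- res$ci95_low <- res$ci95_high <- res$mdrr <- NA_real_
      res$reported <- FALSE; res$reason <- "empty stratum"
      return(res)
    }
    pw <- mdrr(res$py_target, res$py_comparator,
               res$events_target + res$events_comparator,
               gate_threshold = gate_threshold)
    est <- poisson_irr(res$events_target, res$py_target,
                       res$events_comparator, res$py_comparator)
    res$rr <- est$rr; res$ci95_low <- est$ci95_low
    res$ci95_high <- est$ci95_high
    res$mdrr <- pw$mdrr
    if (!pw$estimable) {
      res$reported <- FALSE; res$reason <- "no events"
    } else if (!pw$pass) {
      res$reported <- FALSE; res$reason <- "underpowered (MDRR gate)"
    } else if (!est$estimable) {
      res$reported <- FALSE; res$reason <- "not estimable (zero-event arm)"
    } else {
      res$reported <- TRUE; res$reason <- ""
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
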