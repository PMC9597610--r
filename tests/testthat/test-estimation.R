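test_that("person-time censors at event or follow-up end", {
  coh <- data.frame(person_id = 1:3, arm = "target", index_day = 0L,
                    follow_up_end_day = c(28L, 28L, 12L),
                    censor_reason = "window_end", stringsAsFactors = FALSE)
  pt <- person_time(coh, c(NA, 10L, NA))
  expect_equal(pt, c(28, 10, 12) / 365.25)
  expect_equal(person_time(coh[0, ]), numeric(0))
  bad <- data.frame(person_id = 1L, index_day = 10L,
                    follow_up_end_day = 5L)
  expect_error(person_time(bad), class = "vaxsafety_input_error")
})

test_that("incidence rates reproduce printed per-1000-py arithmetic", {
  r1 <- incidence_rate(827, 136523)
  expect_equal(round(r1$rate_per_1000py, 2), 6.06)
  r2 <- incidence_rate(49, 5037)
  expect_equal(round(r2$rate_per_1000py, 2), 9.73)
  r0 <- incidence_rate(0, 1000)
  expect_identical(r0$rate_per_1000py, 0)
  expect_identical(r0$ci95_low, 0)
  expect_gt(r0$ci95_high, 0)
  expect_error(incidence_rate(5, 0), class = "vaxsafety_input_error")
  expect_true(r1$ci95_low <= r1$rate_per_1000py &&
                r1$rate_per_1000py <= r1$ci95_high)
})

test_that("exact Poisson rate CI has near-nominal coverage (stochastic)", {
  with_seed(12, {
    lambda <- 7; T_ <- 2
    x <- rpois(4000, lambda * T_)
    cover <- vapply(x, function(xi) {
      r <- incidence_rate(xi, T_)
      rate <- lambda * 1000
      r$ci95_low <= rate && rate <= r$ci95_high
    }, logical(1))
    expect_gte(mean(cover), 0.945)
  })
})

test_that("closed-form Poisson IRR equals a regression fit with offset", {
  with_seed(3, {
    for (i in 1:30) {
      xt <- rpois(1, 40) + 1; xc <- rpois(1, 25) + 1
      pt <- runif(1, 50, 500); pc <- runif(1, 50, 500)
      est <- poisson_irr(xt, pt, xc, pc)
      fit <- suppressWarnings(
        glm(c(xt, xc) ~ c(1, 0) + offset(log(c(pt, pc))),
            family = poisson,
            control = glm.control(epsilon = 1e-14, maxit = 100)))
      expect_equal(est$log_rr, unname(coef(fit)[2]), tolerance = 1e-6)
      expect_equal(est$se, unname(sqrt(diag(vcov(fit)))[2]),
                   tolerance = 1e-6)
    }
  })
  # worked cells: target 827/136523 py vs comparator 442/90381 py
  est <- poisson_irr(827, 136523, 442, 90381)
  expect_equal(round(est$rr, 2), 1.24)
  # equal rates -> rr 1, p ~ 1
  eq <- poisson_irr(50, 100, 50, 100)
  expect_equal(eq$rr, 1)
  expect_equal(eq$p, 1, tolerance = 1e-12)
  # zero events in an arm -> not estimable, no continuity correction
  z <- poisson_irr(0, 100, 10, 100)
  expect_false(z$estimable)
  expect_true(is.na(z$rr))
  expect_error(poisson_irr(1, 0, 1, 10), class = "vaxsafety_input_error")
})

test_that("rate and absolute risk differences follow their closed forms", {
  rt <- incidence_rate(827, 136523)   # 6.06 per 1000 py
  rc <- incidence_rate(442, 90381)    # 4.89 per 1000 py
  ird <- rate_difference(rt, rc)
  expect_equal(round(ird$ird_per_1000py, 2), 1.17)
  expect_true(ird$ci95_low <= ird$ird_per_1000py &&
                ird$ird_per_1000py <= ird$ci95_high)
  ard <- absolute_risk_difference(rt, rc)
  direct <- (1 - exp(-(rt$rate_per_1000py / 1000) * 28 / 365.25)) -
    (1 - exp(-(rc$rate_per_1000py / 1000) * 28 / 365.25))
  expect_equal(ard$ard_per_100k, direct * 1e5, tolerance = 1e-12)
  expect_equal(round(ard$ard_per_100k, 2), 8.96, tolerance = 0.01)
  # equal rates -> both zero
  expect_equal(rate_difference(rt, rt)$ird_per_1000py, 0)
  expect_equal(absolute_risk_difference(rt, rt)$ard_per_100k, 0)
  # zero events in both arms -> degenerate zero-width interval
  z <- rate_difference(incidence_rate(0, 10), incidence_rate(0, 10))
  expect_true(z$zero_width)
  expect_identical(z$se, 0)
  # tiny-rate limit: ARD ~ IRD * (28/365.25) * 100
  small_t <- incidence_rate(3, 30000); small_c <- incidence_rate(2, 30000)
  a <- absolute_risk_difference(small_t, small_c)
  i <- rate_difference(small_t, small_c)
  expect_equal(a$ard_per_100k, i$ird_per_1000py * 28 / 365.25 * 100,
               tolerance = 1e-3)
})

test_that("MDRR is monotone, approaches 1, and gates at 5", {
  m1 <- mdrr(10000, 10000, 100)
  m2 <- mdrr(20000, 20000, 200)
  expect_lt(m2$mdrr, m1$mdrr)
  big <- mdrr(1e6, 1e6, 2e6 * 5 / 1000)  # expected counts in the thousands
  expect_lt(big$mdrr, 1.15)
  expect_gt(big$mdrr, 1)
  none <- mdrr(100, 100, 0)
  expect_false(none$estimable)
  tiny <- mdrr(10, 10, 1)
  expect_false(tiny$pass)
  expect_error(mdrr(0, 10, 5), class = "vaxsafety_input_error")
})

test_that("MDRR bisection agrees with the simulation power oracle", {
  rate <- 5 / 1000; pyt <- pyc <- 10000
  sol <- mdrr(pyt, pyc, rate * (pyt + pyc))
  p_at <- sim_power(sol$mdrr, rate, pyt, pyc, B = 10000, seed = 41)
  # slope of the power curve around the solution
  d <- 0.05
  slope <- (sim_power(sol$mdrr + d, rate, pyt, pyc, 10000, 42) -
              sim_power(sol$mdrr - d, rate, pyt, pyc, 10000, 43)) / (2 * d)
  se_theta <- sqrt(0.8 * 0.2 / 10000) / slope
  expect_lt(abs(p_at - 0.80) * abs(1 / slope), 2 * se_theta + 0.01)
})

test_that("stratified estimates partition events and suppress weak strata", {
  with_seed(8, {
    n <- 4000
    d <- data.frame(arm = sample(c("target", "comparator"), n, TRUE),
                    days = 28,
                    event = rbinom(n, 1, 0.05),
                    age = sample(30:59, n, TRUE),
                    sex = sample(c("female", "male"), n, TRUE),
                    stringsAsFactors = FALSE)
    s <- stratified_estimates(d)
    expect_equal(sum(s$events_target) + sum(s$events_comparator),
                 sum(d$event))
    expect_identical(nrow(s), 6L)  # 3 age bands x 2 sexes
    # single-stratum data reduce to the unstratified estimate
    d1 <- d; d1$age <- 45; d1$sex <- "female"
    s1 <- stratified_estimates(d1)
    expect_identical(nrow(s1), 1L)
    direct <- poisson_irr(sum(d1$event[d1$arm == "target"]),
                          sum(d1$days[d1$arm == "target"]) / 365.25,
                          sum(d1$event[d1$arm == "comparator"]),
                          sum(d1$days[d1$arm == "comparator"]) / 365.25)
    expect_equal(s1$rr, direct$rr, tolerance = 1e-12)
    # a stratum with no events is suppressed with a reason
    d0 <- d[1:50, ]; d0$event <- 0; d0$age <- 85
    s0 <- stratified_estimates(rbind(d, d0))
    row85 <- s0[grepl("^80", s0$stratum), ]
    expect_true(all(!row85$reported))
  })
})

test_that("effect-estimate CIs cover the generating rate ratio (stochastic)", {
  with_seed(90, {
    theta <- log(1.5)
    lam_c <- 30
    cover <- replicate(600, {
      xc <- rpois(1, lam_c); xt <- rpois(1, lam_c * 1.5)
      if (xc == 0 || xt == 0) return(NA)
      e <- poisson_irr(xt, 1, xc, 1)
      e$ci95_low <= 1.5 && 1.5 <= e$ci95_high
    })
    expect_gt(mean(cover, na.rm = TRUE), 0.92)
  })
})
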