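test_that("propensity model shrinks null covariates and recovers signs", {
  with_seed(31, {
    n <- 6000
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.3), c = rnorm(n))
    # covariates independent of arm: near-zero slopes, AUC ~ 0.5
    arm0 <- ifelse(rbinom(n, 1, 0.5) == 1, "target", "comparator")
    m0 <- fit_propensity_model(x, arm0, seed = 1)
    expect_true(all(abs(m0$coefficients) < 0.15))
    lg <- predict_logit(m0, x)
    auc <- mean(outer(lg[arm0 == "target"], lg[arm0 == "comparator"], ">")
                + 0.5 * outer(lg[arm0 == "target"],
                              lg[arm0 == "comparator"], "=="))
    expect_lt(abs(auc - 0.5), 0.05)
    # strong positive assignment effect on a: recovered sign
    p <- plogis(-0.2 + 1.2 * x[, "a"])
    arm1 <- ifelse(rbinom(n, 1, p) == 1, "target", "comparator")
    m1 <- fit_propensity_model(x, arm1, seed = 1)
    expect_gt(m1$coefficients[["a"]], 0.5)
  })
})

test_that("full-shrinkage limit zeroes slopes and leaves prevalence logit", {
  with_seed(5, {
    n <- 2000
    x <- cbind(a = rnorm(n), b = rnorm(n))
    arm <- ifelse(rbinom(n, 1, 0.3) == 1, "target", "comparator")
    m <- fit_propensity_model(x, arm, lambda_grid = 1e6)
    expect_true(all(m$coefficients == 0))
    expect_equal(m$intercept, qlogis(mean(arm == "target")),
                 tolerance = 1e-6)
  })
  expect_error(fit_propensity_model(matrix(rnorm(20), 10),
                                    rep("target", 10)),
               class = "vaxsafety_input_error")
})

test_that("logit prediction is linear and ignores unseen covariates", {
  with_seed(9, {
    x <- cbind(a = rnorm(500), b = rnorm(500))
    arm <- ifelse(rbinom(500, 1, plogis(x[, 1])) == 1, "target",
                  "comparator")
    m <- fit_propensity_model(x, arm, seed = 2)
    lg <- predict_logit(m, x)
    expect_equal(lg, m$intercept + as.numeric(x %*% m$coefficients),
                 tolerance = 1e-10)
    # identical rows -> identical logits; all-zero row -> intercept
    x2 <- rbind(x[1, ], x[1, ], c(a = 0, b = 0))
    lg2 <- predict_logit(m, x2)
    expect_equal(lg2[1], lg2[2])
    expect_equal(lg2[3], m$intercept)
    # an extra covariate unseen at fit time contributes nothing
    x3 <- cbind(x, z = rnorm(500))
    expect_equal(predict_logit(m, x3), lg)
  })
})

test_that("degenerate equal-logit matching fills sets by lowest id", {
  ms <- greedy_match(rep(0.5, 3), rep(0.5, 12),
                     id_target = c(101L, 102L, 103L),
                     id_comparator = 201:212, seed = 1)
  expect_identical(attr(ms, "caliper"), 0)
  sets <- sets_as_list(ms)
  expect_length(sets, 3)
  expect_true(all(lengths(sets) == 4))
  # every candidate used exactly once, lowest ids first overall
  expect_setequal(unlist(sets), 201:212)
})

test_that("6-node instance matches the hand-worked greedy result", {
  ms <- greedy_match(c(0.0, 1.0), c(0.05, 0.90, 5.0),
                     id_target = c(1L, 2L), id_comparator = c(11L, 12L, 13L),
                     caliper_sd = 0.1 / sd(c(0, 1, 0.05, 0.9, 5)),
                     seed = 3)
  sets <- sets_as_list(ms)
  expect_identical(sets[["1"]], 11L)  # 0.0 -> 0.05
  expect_identical(sets[["2"]], 12L)  # 1.0 -> 0.90
  expect_false(13L %in% unlist(sets)) # 5.0 unmatched
})

test_that("greedy matching equals the step-by-step oracle on small instances", {
  with_seed(99, {
    for (i in 1:400) {
      nb <- sample(1:5, 1); nc <- nb + sample(0:6, 1)
      bl <- round(rnorm(nb), 2)
      cl <- round(rnorm(nc), 2)
      bid <- sample(1000:9999, nb); cid <- sample(1:999, nc)
      seed <- sample.int(1e6, 1)
      caliper_sd <- runif(1, 0.1, 1)
      ms <- greedy_match(bl, cl, bid, cid, caliper_sd = caliper_sd,
                         seed = seed)
      caliper <- caliper_sd * sd(c(bl, cl))
      orders <- match_orders(nb, 4L, seed)
      want <- oracle_greedy(bl, bid, cl, cid, caliper, 4L, orders)
      got <- sets_as_list(ms)
      if (!length(want)) {
        expect_length(got, 0)
      } else {
        expect_identical(lapply(got[order(names(got))], sort),
                         lapply(want[order(names(want))], sort))
      }
    }
  })
})

test_that("matching output is a valid partial matching (property)", {
  with_seed(17, {
    for (i in 1:20) {
      nt <- sample(20:80, 1); nc <- sample(20:200, 1)
      lt <- rnorm(nt); lc <- rnorm(nc, mean = 0.3)
      ms <- greedy_match(lt, lc, id_target = seq_len(nt),
                         id_comparator = nt + seq_len(nc),
                         seed = i)
      # no candidate reused; ratio bound respected; pairs inside caliper
      cand <- ms$person_id[ms$role == "candidate"]
      expect_identical(anyDuplicated(cand), 0L)
      sizes <- table(ms$set_id[ms$role == "candidate"])
      expect_true(all(sizes >= 1 & sizes <= 4))
      cal <- attr(ms, "caliper")
      logit_of <- c(stats::setNames(lt, seq_len(nt)),
                    stats::setNames(lc, nt + seq_len(nc)))
      for (s in unique(ms$set_id)) {
        rows <- ms[ms$set_id == s, ]
        b <- logit_of[as.character(rows$person_id[rows$role == "base"])]
        cc <- logit_of[as.character(
          rows$person_id[rows$role == "candidate"])]
        expect_true(all(abs(cc - b) <= cal + 1e-12))
      }
    }
  })
})

test_that("reverse matching is used when the target cohort is larger", {
  ms <- greedy_match(rnorm(50), rnorm(10), id_target = 1:50,
                     id_comparator = 101:110, seed = 2)
  expect_identical(attr(ms, "orientation"), "reverse")
  mp <- matched_persons(ms)
  expect_true(all(mp$comparator %in% 101:110))
  expect_true(all(mp$target %in% 1:50))
  # pigeonhole: with everything inside the caliper, the matched candidate
  # count is capped by the candidate pool
  ms2 <- greedy_match(seq(0, 1, length.out = 5), c(0.1, 0.2),
                      id_target = 1:5, id_comparator = 11:12,
                      caliper_sd = 10, seed = 2)
  expect_identical(sum(ms2$role == "candidate"), 5L)  # reverse: targets
  expect_identical(sum(ms2$role == "base"), 2L)
})

test_that("SMD formula, zero-variance handling and the balance gate", {
  # binary covariate p_t = 0.6, p_c = 0.5 -> SMD = 0.1/sqrt(0.245)
  cov <- structure(list(
    matrix = Matrix::Matrix(matrix(c(rep(1, 6), rep(0, 4),
                                     rep(1, 5), rep(0, 5)), ncol = 1,
                                   dimnames = list(NULL, "flag")),
                            sparse = TRUE),
    meta = data.frame(covariate_id = "flag", label = "flag",
                      type = "binary"),
    person_id = 1:20), class = "covariate_matrix")
  smd <- compute_smd(cov, 1:10, 11:20)
  expect_equal(smd$smd, 0.1 / sqrt((0.24 + 0.25) / 2), tolerance = 1e-12)
  # identical distributions -> 0; constant covariate -> 0
  smd0 <- compute_smd(cov, 1:10, 1:10)
  expect_identical(smd0$smd, 0)
  # constant in both arms but different values -> undefined flag
  cov2 <- cov
  cov2$matrix[, 1] <- c(rep(1, 10), rep(0, 10))
  smd2 <- compute_smd(cov2, 1:10, 11:20)
  expect_true(smd2$undefined)
  expect_true(is.na(smd2$smd))

  gate <- balance_gate(data.frame(covariate_id = c("a", "b"),
                                  smd_post = c(0.09, -0.05),
                                  undefined = FALSE))
  expect_true(gate$pass)
  gate2 <- balance_gate(data.frame(covariate_id = c("a", "b"),
                                   smd_post = c(0.15, 0.02),
                                   undefined = FALSE))
  expect_false(gate2$pass)
  expect_identical(gate2$offending, "a")
  # strictly below 0.1: exactly 0.1 fails
  gate3 <- balance_gate(data.frame(covariate_id = "a", smd_post = 0.1,
                                   undefined = FALSE))
  expect_false(gate3$pass)
})

test_that("matching reduces covariate imbalance on confounded data", {
  cfg <- balance_scenario_config(n = 20000)
  db <- generate_database(cfg, seed = 77)
  ct <- build_cohort(db, "ChAdOx1-S", 1L, arm = "target")
  cc <- build_cohort(db, "BNT162b2", 1L, arm = "comparator")
  cov <- rbind_covariates(extract_covariates(db, ct),
                          extract_covariates(db, cc))
  arm <- c(rep("target", nrow(ct)), rep("comparator", nrow(cc)))
  m <- fit_propensity_model(cov, arm, lambda_grid = c(1e-4, 1e-5) / 2e4,
                            seed = 7)
  lg <- predict_logit(m, cov)
  ms <- greedy_match(lg[arm == "target"], lg[arm == "comparator"],
                     ct$person_id, cc$person_id, seed = 7)
  mp <- matched_persons(ms)
  pre <- compute_smd(cov, ct$person_id, cc$person_id)
  post <- compute_smd(cov, mp$target, mp$comparator)
  expect_lt(mean(abs(post$smd), na.rm = TRUE),
            mean(abs(pre$smd), na.rm = TRUE))
})
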