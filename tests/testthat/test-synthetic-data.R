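test_that("generation is deterministic for a fixed (config, seed)", {
  cfg <- quick_config(n = 1500)
  a <- generate_database(cfg, seed = 11)
  b <- generate_database(cfg, seed = 11)
  expect_identical(a$person, b$person)
  expect_identical(a$vaccination, b$vaccination)
  expect_identical(a$event, b$event)
  expect_identical(a$measurement, b$measurement)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_database(cfg, seed = 12)
  expect_false(identical(a$event, c$event))
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(sim_config(outcome_spec = data.frame(
    name = "x", baseline_rate = -1, true_rr = 1)),
    class = "vaxsafety_config_error")
  expect_error(sim_config(outcome_spec = data.frame(
    name = "x", baseline_rate = 1, true_rr = 0)),
    class = "vaxsafety_config_error")
  expect_error(sim_config(study_start_day = 10, study_end_day = 10),
               class = "vaxsafety_config_error")
  expect_error(sim_config(crossover_prob = 2),
               class = "vaxsafety_config_error")
  expect_error(sim_config(systematic_error = list(mean = 0, sd = NaN)),
               class = "vaxsafety_config_error")
})

test_that("no event falls outside its person's observation period", {
  db <- generate_database(quick_config(n = 3000), seed = 5)
  expect_silent(validate_database(db))
  m <- match(db$event$person_id, db$person$person_id)
  expect_true(all(db$event$day >= db$person$observation_start_day[m]))
  expect_true(all(db$event$day <= db$person$observation_end_day[m]))
})

crude_arm_rates <- function(db, concept) {
  v <- db$vaccination[db$vaccination$dose_number == 1L, ]
  p <- db$person[match(v$person_id, db$person$person_id), ]
  years <- (p$observation_end_day - p$observation_start_day) / 365.25
  ev <- db$event[db$event$concept == concept, ]
  cnt <- tabulate(match(ev$person_id, v$person_id), nbins = nrow(v))
  tgt <- v$brand == db$config$target_brand
  list(x_t = sum(cnt[tgt]), t_t = sum(years[tgt]),
       x_c = sum(cnt[!tgt]), t_c = sum(years[!tgt]))
}

test_that("event-count ratios recover the configured true rate ratio", {
  # no confounding, no systematic error; whole-observation crude ratio
  for (rr in c(1, 2)) {
    cfg <- sim_config(n_persons = 30000, assignment_intercept = 0,
                      assignment_coefficients = numeric(0),
                      outcome_coefficients = numeric(0),
                      outcome_spec = data.frame(name = "evt",
                                                baseline_rate = 5 / 1000,
                                                true_rr = rr),
                      n_negative_controls = 0)
    db <- generate_database(cfg, seed = 100 + rr)
    cells <- crude_arm_rates(db, "evt")
    est <- log((cells$x_t / cells$t_t) / (cells$x_c / cells$t_c))
    se <- sqrt(1 / cells$x_t + 1 / cells$x_c)
    expect_lt(abs(est - log(rr)), 3 * se)
  }
})

test_that("injected systematic error shifts all outcomes' log-RRs by its mean", {
  cfg <- sim_config(n_persons = 30000, assignment_intercept = 0,
                    assignment_coefficients = numeric(0),
                    outcome_coefficients = numeric(0),
                    n_negative_controls = 30,
                    nc_baseline_rate = 20 / 1000,
                    systematic_error = list(mean = 0.3, sd = 0.05))
  db <- generate_database(cfg, seed = 21)
  ncs <- negative_control_concepts(db)
  est <- vapply(ncs, function(cc) {
    cells <- crude_arm_rates(db, cc)
    log((cells$x_t / cells$t_t) / (cells$x_c / cells$t_c))
  }, numeric(1))
  expect_gte(length(est), 30)
  # mean over >=30 NCs: Monte-Carlo SE ~ sd/sqrt(m)
  expect_lt(abs(mean(est) - 0.3), 3 * stats::sd(est) / sqrt(length(est)))
})

test_that("database round-trips through write/read identically", {
  db <- generate_database(quick_config(n = 400), seed = 3)
  dir <- withr::local_tempdir()
  write_database(db, dir)
  back <- read_database(dir)
  for (tab in c("person", "vaccination", "event", "measurement")) {
    want <- db[[tab]][, vaxsafety:::required_columns[[tab]], drop = FALSE]
    rownames(want) <- NULL
    expect_equal(back[[tab]], want, ignore_attr = TRUE)
  }
  expect_equal(back$ground_truth$outcomes, db$ground_truth$outcomes,
               tolerance = 1e-12)
})

test_that("reader rejects malformed tables with named parse errors", {
  db <- generate_database(quick_config(n = 200), seed = 3)
  dir <- withr::local_tempdir()
  write_database(db, dir)

  # duplicated (person, dose) row
  v <- utils::read.csv(file.path(dir, "vaccination.csv"))
  utils::write.csv(rbind(v, v[1, ]), file.path(dir, "vaccination.csv"),
                   row.names = FALSE)
  expect_error(read_database(dir), "one vaccination record per",
               class = "vaxsafety_invariant_error")
  utils::write.csv(v, file.path(dir, "vaccination.csv"), row.names = FALSE)

  # non-integer day with file+line context
  e <- utils::read.csv(file.path(dir, "event.csv"))
  e$day[2] <- 3.5
  utils::write.csv(e, file.path(dir, "event.csv"), row.names = FALSE)
  err <- tryCatch(read_database(dir), error = identity)
  expect_s3_class(err, "vaxsafety_parse_error")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "event.csv")

  # missing column / missing file
  utils::write.csv(e[, c("person_id", "day")], file.path(dir, "event.csv"),
                   row.names = FALSE)
  expect_error(read_database(dir), "missing required column",
               class = "vaxsafety_parse_error")
  unlink(file.path(dir, "event.csv"))
  expect_error(read_database(dir), "missing table file",
               class = "vaxsafety_parse_error")
})

test_that("an empty events table is a valid database with zero events", {
  db <- generate_database(quick_config(n = 200), seed = 3)
  dir <- withr::local_tempdir()
  write_database(db, dir)
  e <- utils::read.csv(file.path(dir, "event.csv"))
  utils::write.csv(e[0, ], file.path(dir, "event.csv"), row.names = FALSE)
  back <- read_database(dir)
  expect_identical(nrow(back$event), 0L)
})

test_that("simulation configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_persons: 500",
    "assignment_intercept: -1.0",
    "assignment_coefficients:",
    "  age: 0.2",
    "  hypertension: 0.4",
    "outcome_coefficients:",
    "  age: 0.3",
    "n_negative_controls: 4",
    "outcome_spec:",
    "  - name: thrombocytopenia",
    "    baseline_rate: 0.02",
    "    true_rr: 1.5",
    "covariate_spec:",
    "  comorbidities:",
    "    hypertension: 0.3",
    "    diabetes: 0.1"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "vsd_config")
  expect_identical(cfg$n_persons, 500L)
  expect_equal(cfg$outcome_spec$true_rr, 1.5)
  expect_equal(cfg$covariate_spec$comorbidities[["hypertension"]], 0.3)
  # unspecified covariate_spec entries keep their defaults
  expect_true(!is.null(cfg$covariate_spec$utilisation_means))
  db <- generate_database(cfg, seed = 1)
  expect_identical(nrow(db$person), 500L)
})
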