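mk_event_db <- function(events, measurements = NULL) {
  pids <- unique(c(events$person_id,
                   if (!is.null(measurements)) measurements$person_id, 1L))
  person <- data.frame(person_id = sort(pids), sex = "female",
                       birth_year = 1970L,
                       observation_start_day = -2000L,
                       observation_end_day = 2000L, death_day = NA_integer_,
                       stringsAsFactors = FALSE)
  structure(list(
    person = person,
    vaccination = data.frame(person_id = integer(0), brand = character(0),
                             dose_number = integer(0), day = integer(0)),
    event = events,
    measurement = measurements %||%
      data.frame(person_id = integer(0), day = integer(0),
                 value = numeric(0)),
    ground_truth = NULL), class = "vsd_database")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

entry <- function(pid = 1L, index = 0L, fue = 28L) {
  list(person_id = pid, index_day = index, follow_up_end_day = fue)
}

test_that("first-event ascertainment respects window and composites", {
  reg <- default_outcome_registry()
  db <- mk_event_db(data.frame(
    person_id = c(1L, 1L), concept = c("deep_vein_thrombosis",
                                       "pulmonary_embolism"),
    day = c(5L, 3L), stringsAsFactors = FALSE))
  # composite takes the earliest member day
  expect_identical(
    ascertain_first_event(db, entry(), "venous_thromboembolism", reg), 3L)
  expect_identical(
    ascertain_first_event(db, entry(), "deep_vein_thrombosis", reg), 5L)
  # day 29 with full follow-up: outside the window
  db2 <- mk_event_db(data.frame(person_id = 1L, concept = "ischaemic_stroke",
                                day = 29L, stringsAsFactors = FALSE))
  expect_true(is.na(
    ascertain_first_event(db2, entry(), "ischaemic_stroke", reg)))
  # event at day 10 but follow-up censored at day 7 (death)
  db3 <- mk_event_db(data.frame(person_id = 1L, concept = "ischaemic_stroke",
                                day = 10L, stringsAsFactors = FALSE))
  expect_true(is.na(
    ascertain_first_event(db3, entry(fue = 7L), "ischaemic_stroke", reg)))
  # an event on the index day itself is not at risk
  db4 <- mk_event_db(data.frame(person_id = 1L, concept = "ischaemic_stroke",
                                day = 0L, stringsAsFactors = FALSE))
  expect_true(is.na(
    ascertain_first_event(db4, entry(), "ischaemic_stroke", reg)))
  expect_error(ascertain_first_event(db, entry(), "nonesuch", reg),
               class = "vaxsafety_input_error")
})

test_that("composite day equals the minimum over member days (property)", {
  reg <- default_outcome_registry()
  with_seed(42, {
    for (i in 1:25) {
      days_dvt <- sample(-10:40, sample(0:3, 1))
      days_pe <- sample(-10:40, sample(1:3, 1))
      ev <- rbind(
        data.frame(person_id = rep(1L, length(days_dvt)),
                   concept = rep("deep_vein_thrombosis",
                                 length(days_dvt)),
                   day = days_dvt),
        data.frame(person_id = rep(1L, length(days_pe)),
                   concept = rep("pulmonary_embolism", length(days_pe)),
                   day = days_pe))
      db <- mk_event_db(ev)
      got <- ascertain_first_event(db, entry(), "venous_thromboembolism",
                                   reg)
      inwin <- c(days_dvt, days_pe)
      inwin <- inwin[inwin > 0 & inwin <= 28]
      want <- if (length(inwin)) min(inwin) else NA_integer_
      expect_identical(got, as.integer(want))
    }
  })
})

test_that("prior-history exclusion removes exactly pre-index cases", {
  reg <- default_outcome_registry()
  db <- mk_event_db(data.frame(
    person_id = c(1L, 2L, 3L),
    concept = c("deep_vein_thrombosis", "deep_vein_thrombosis",
                "myocardial_infarction"),
    day = c(-700L, 5L, -10L), stringsAsFactors = FALSE))
  cohort <- data.frame(person_id = 1:3, arm = "target", index_day = 0L,
                       follow_up_end_day = 28L,
                       censor_reason = "window_end", stringsAsFactors = FALSE)
  # prior DVT two years back excludes person 1 from the DVT analysis
  out <- exclude_prior_history(cohort, db, "deep_vein_thrombosis", reg)
  expect_identical(out$person_id, c(2L, 3L))
  # person with prior DVT retained when analysing myocardial infarction
  out_mi <- exclude_prior_history(cohort, db, "myocardial_infarction", reg)
  expect_identical(out_mi$person_id, c(1L, 2L))
  # no events at all: cohort unchanged
  out_none <- exclude_prior_history(cohort, db, "pulmonary_embolism", reg)
  expect_identical(out_none, cohort)
})

test_that("thrombocytopenia day detection unions diagnoses and low counts", {
  db <- mk_event_db(
    data.frame(person_id = 1L, concept = "thrombocytopenia_dx", day = 7L,
               stringsAsFactors = FALSE),
    data.frame(person_id = 1L, day = c(3L, 9L), value = c(120, 200)))
  expect_identical(detect_thrombocytopenia_days(db, 1L, 150), c(3L, 7L))
  # strict "<": 120 not low at threshold 100; diagnosis day remains
  expect_identical(detect_thrombocytopenia_days(db, 1L, 100), 7L)
  # diagnosis-only evidence counts
  db2 <- mk_event_db(data.frame(person_id = 1L,
                                concept = "thrombocytopenia_dx", day = 4L,
                                stringsAsFactors = FALSE))
  expect_identical(detect_thrombocytopenia_days(db2, 1L, 150), 4L)
})

test_that("TTS classification matches the pair-scan oracle", {
  tts10 <- tts_definition("venous_thromboembolism")
  tts5 <- tts_definition("venous_thromboembolism",
                         concurrency_window_days = 5L)
  # worked boundary cases
  expect_true(classify_tts(20L, 25L, tts10))
  expect_false(classify_tts(20L, 32L, tts10))   # 12 days after, window 10
  expect_false(classify_tts(20L, 13L, tts5))    # 7 days before, window 5
  expect_true(classify_tts(20L, 30L, tts10))    # exactly at the boundary
  expect_false(classify_tts(20L, integer(0), tts10))
  # property: equals brute-force scan over random fixtures
  with_seed(7, {
    for (i in 1:200) {
      ed <- sample(1:28, 1)
      td <- sample(-20:60, sample(0:5, 1))
      w <- sample(c(5L, 10L), 1)
      tts <- tts_definition("venous_thromboembolism",
                            concurrency_window_days = w)
      expect_identical(classify_tts(ed, td, tts), oracle_tts(ed, td, w))
    }
  })
})

test_that("first TTS event scans thromboembolic events in day order", {
  reg <- default_outcome_registry()
  ev <- data.frame(
    person_id = c(1L, 1L, 1L),
    concept = c("deep_vein_thrombosis", "pulmonary_embolism",
                "thrombocytopenia_dx"),
    day = c(5L, 15L, 16L), stringsAsFactors = FALSE)
  db <- mk_event_db(ev)
  tts <- tts_definition("venous_thromboembolism")
  # day-5 event has no concurrent thrombocytopenia (|16-5| > 10); day-15 has
  expect_identical(ascertain_first_tts(db, entry(), tts, reg), 15L)
  # measurement-based evidence, concurrency may extend past day 28
  db2 <- mk_event_db(
    data.frame(person_id = 1L, concept = "pulmonary_embolism", day = 27L,
               stringsAsFactors = FALSE),
    data.frame(person_id = 1L, day = 35L, value = 90))
  expect_identical(ascertain_first_tts(db2, entry(), tts, reg), 27L)
  # the 100k-threshold variant ignores a 120 measurement
  db3 <- mk_event_db(
    data.frame(person_id = 1L, concept = "pulmonary_embolism", day = 10L,
               stringsAsFactors = FALSE),
    data.frame(person_id = 1L, day = 12L, value = 120))
  tts100 <- tts_definition("venous_thromboembolism",
                           platelet_threshold = 100)
  expect_true(is.na(ascertain_first_tts(db3, entry(), tts100, reg)))
  expect_identical(ascertain_first_tts(db3, entry(), tts, reg), 10L)
})

test_that("outcome definitions validate composites and NC flags", {
  expect_error(outcome_definition("nc", "c", composite_of = "x",
                                  negative_control = TRUE),
               class = "vaxsafety_config_error")
  expect_error(outcome_definition("empty"),
               class = "vaxsafety_config_error")
  reg <- default_outcome_registry()
  expect_setequal(
    vaxsafety:::resolve_concepts("arterial_thromboembolism", reg),
    c("ischaemic_stroke", "myocardial_infarction", "intestinal_infarction"))
})

test_that("outcome definitions round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "deep_vein_thrombosis:",
    "  concepts: [deep_vein_thrombosis]",
    "pulmonary_embolism:",
    "  concepts: [pulmonary_embolism]",
    "venous_thromboembolism:",
    "  composite_of: [deep_vein_thrombosis, pulmonary_embolism]",
    "nc_sprain:",
    "  concepts: [ankle_sprain]",
    "  negative_control: true"), path)
  reg <- read_outcome_definitions(path)
  expect_named(reg, c("deep_vein_thrombosis", "pulmonary_embolism",
                      "venous_thromboembolism", "nc_sprain"))
  expect_true(reg$nc_sprain$negative_control)
  expect_setequal(vaxsafety:::resolve_concepts("venous_thromboembolism", reg),
                  c("deep_vein_thrombosis", "pulmonary_embolism"))
})
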