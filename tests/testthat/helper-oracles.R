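# Independent oracle implementations and shared scenario builders.

with_seed <- vaxsafety:::with_seed

# Step-by-step greedy matching oracle: O(n^2) literal transcription of the
# matching contract, independent of the linked-list implementation. Takes
# the round visiting orders explicitly.
oracle_greedy <- function(base_logit, base_id, cand_logit, cand_id,
                          caliper, max_ratio, orders) {
  avail <- rep(TRUE, length(cand_logit))
  matched <- stats::setNames(vector("list", length(base_logit)),
                             as.character(base_id))
  for (r in seq_len(max_ratio)) {
    for (b in orders[, r]) {
      if (r > 1 && length(matched[[b]]) == 0) next
      d <- abs(cand_logit - base_logit[b])
      d[!avail] <- Inf
      if (min(d) > caliper) next
      cand <- which(d == min(d))
      cand <- cand[which.min(cand_id[cand])]
      avail[cand] <- FALSE
      matched[[b]] <- c(matched[[b]], cand_id[cand])
    }
  }
  matched[lengths(matched) > 0]
}

# Reproduce the visiting orders greedy_match() derives from its seed.
match_orders <- function(n_base, max_ratio, seed) {
  o <- with_seed(seed, vapply(seq_len(max_ratio),
                              function(r) sample.int(n_base),
                              integer(n_base)))
  if (n_base == 1L) o <- matrix(o, nrow = 1L)
  o
}

# greedy_match() result as a list base_id -> candidate ids (in match order)
sets_as_list <- function(ms) {
  out <- list()
  for (s in unique(ms$set_id)) {
    rows <- ms[ms$set_id == s, ]
    b <- rows$person_id[rows$role == "base"]
    out[[as.character(b)]] <- rows$person_id[rows$role == "candidate"]
  }
  out
}

# Monte-Carlo power of the Wald Poisson IRR test at rate ratio theta
sim_power <- function(theta, rate, py_t, py_c, B = 10000, seed = 1) {
  with_seed(seed, {
    xt <- stats::rpois(B, theta * rate * py_t)
    xc <- stats::rpois(B, rate * py_c)
    ok <- xt > 0 & xc > 0
    z <- abs(log((xt / py_t) / (xc / py_c))) / sqrt(1 / xt + 1 / xc)
    z[!ok] <- 0
    mean(z > stats::qnorm(0.975))
  })
}

# Brute-force TTS classifier: scan all (event, thrombocytopenia-day) pairs
oracle_tts <- function(thrombo_day, tdays, window) {
  hit <- FALSE
  for (d in tdays)
    for (e in thrombo_day)
      if (abs(d - e) <= window) hit <- TRUE
  hit
}

# small, fast generator configuration for unit tests
quick_config <- function(n = 4000, ...) {
  sim_config(n_persons = n, n_negative_controls = 5, ...)
}

# saturated minority-target scenario: comparator pool large enough to fill
# the 1:4 ratio, the regime in which unweighted variable-ratio matching
# balances
balance_scenario_config <- function(n = 60000) {
  sim_config(n_persons = n, assignment_intercept = -2.6,
             n_negative_controls = 0)
}

# end-to-end recovery scenario: majority target arm (reverse matching with
# a saturated candidate pool), one outcome with true RR 1.33 at
# 5/1000 person-years, measured confounding only
recovery_scenario_config <- function(n = 100000, true_rr = 1.33) {
  sim_config(
    n_persons = n, assignment_intercept = 1.9,
    assignment_coefficients = c(age = 0.2, sex_female = -0.15,
                                hypertension = 0.35, diabetes = 0.3,
                                heart_failure = 0.2, drug = 0.04),
    outcome_spec = data.frame(name = "thrombocytopenia",
                              baseline_rate = 5 / 1000,
                              true_rr = true_rr,
                              stringsAsFactors = FALSE),
    n_negative_controls = 30,
    covariate_spec = list(
      age_mean = 52, age_sd = 16, age_min = 18, age_max = 99,
      p_female = 0.55,
      comorbidities = c(hypertension = 0.25, diabetes = 0.10,
                        heart_failure = 0.04, vascular_disease = 0.06,
                        stroke = 0.03, cancer = 0.06, renal_disease = 0.03),
      utilisation_means = c(drug = 1.5, procedure = 0.6, measurement = 1),
      history_mean_days = 1500, p_short_history = 0.05))
}

two_arm_comparison <- function(name = "cmp") {
  list(name = name,
       target = list(brand = "ChAdOx1-S", dose = 1L),
       comparator = list(brand = "BNT162b2", dose = 1L))
}

# tiny hand-built database for boundary tests
toy_db <- function() {
  person <- data.frame(
    person_id = 1:6,
    sex = c("female", "male", "female", "male", "female", "male"),
    birth_year = c(1960L, 1990L, 1945L, 2005L, 1980L, 1950L),
    observation_start_day = c(-1000L, -200L, -800L, -1000L, -1000L, -600L),
    observation_end_day = c(400L, 400L, 40L, 400L, 15L, 400L),
    death_day = c(NA, NA, NA, NA, 15L, NA),
    stringsAsFactors = FALSE)
  vaccination <- data.frame(
    person_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 6L),
    brand = c("A", "A", "A", "A", "A", "A", "A", "A"),
    dose_number = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L),
    day = c(10L, 80L, 10L, 10L, 10L, 10L, 10L, 20L),
    stringsAsFactors = FALSE)
  event <- data.frame(person_id = integer(0), concept = character(0),
                      day = integer(0), stringsAsFactors = FALSE)
  measurement <- data.frame(person_id = integer(0), day = integer(0),
                            value = numeric(0), stringsAsFactors = FALSE)
  structure(list(person = person, vaccination = vaccination,
                 event = event, measurement = measurement,
                 ground_truth = NULL),
            class = "vsd_database")
}
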