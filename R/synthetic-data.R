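#' Simulation configuration for a synthetic vaccination database
#'
#' Describes a two-arm covid-19 vaccination database with known confounding
#' structure, known true incidence rate ratios, negative-control outcomes,
#' and (optionally) a multiplicative systematic ascertainment error injected
#' into the target arm. The generator draws outcome events from a Poisson
#' process whose rate is \code{baseline * covariate multiplier * true RR (if
#' target arm) * systematic-error multiplier}, which is exactly the data
#' model the downstream Poisson estimation assumes.
#'
#' @param n_persons number of persons to simulate.
#' @param study_start_day,study_end_day integer day indices (day 0 = study
#'   start epoch); vaccinations and follow-up happen inside this window.
#' @param target_brand,comparator_brand brand labels; one of
#'   \code{"ChAdOx1-S"}, \code{"BNT162b2"}, \code{"mRNA-1273"},
#'   \code{"Ad26.COV2.S"} (other labels are permitted).
#' @param rollout_days length-2 integer vector; dose-1 days are drawn
#'   uniformly in this range.
#' @param assignment_intercept,assignment_coefficients log-odds of receiving
#'   the target brand: intercept plus named per-covariate weights. Recognised
#'   names: \code{age} (per 10 years, centred at 50), \code{sex_female}, any
#'   comorbidity name from \code{covariate_spec$comorbidities}, and any
#'   utilisation concept (\code{drug}, \code{procedure}, \code{measurement};
#'   weight per record in the prior 6 months).
#' @param covariate_spec list with elements \code{age_mean}, \code{age_sd},
#'   \code{age_min}, \code{age_max}, \code{p_female}, \code{comorbidities}
#'   (named prevalences), \code{utilisation_means} (named 6-month means),
#'   \code{history_mean_days}, \code{p_short_history}.
#' @param outcome_spec data.frame with columns \code{name},
#'   \code{baseline_rate} (events per person-year) and \code{true_rr}
#'   (target vs comparator rate ratio, > 0).
#' @param outcome_coefficients named log-linear covariate effects on all
#'   outcome hazards (same naming as \code{assignment_coefficients}); the
#'   overlap with the assignment model is what creates confounding.
#' @param n_negative_controls number of negative-control outcomes, all with
#'   true rate ratio 1 (concepts \code{nc_001}, \code{nc_002}, ...).
#' @param nc_baseline_rate baseline rate of each negative control, in
#'   events per person-year. Negative controls stand in for common
#'   conditions unrelated to vaccination, so the default is an order of
#'   magnitude above the thromboembolic outcome rates.
#' @param systematic_error \code{NULL}, or \code{list(mean=, sd=)}: a
#'   per-outcome multiplicative ascertainment bias in the target arm, drawn
#'   once per outcome (including negative controls) from a normal
#'   distribution on the log-RR scale. This is the error structure the
#'   empirical null of the calibration module models.
#' @param censoring \code{list(disenrol_hazard=, death_hazard=)}, per year.
#' @param dose2 \code{list(prob=, gap_mean=, gap_min=)}: probability of a
#'   second dose and the dose gap distribution (days).
#' @param crossover_prob probability that a dose-2 record carries the other
#'   brand (default 0; used only to exercise the exclusion rule).
#' @param short_gap_prob probability that the dose gap is drawn from 1..14
#'   days (default 0; exercises the 14-day exclusion rule).
#' @param platelet_spec list controlling platelet measurements:
#'   \code{p_measured_near_event}, \code{p_low_near_event},
#'   \code{normal_mean} (250), \code{normal_sd} (50), \code{low_mean} (90),
#'   \code{low_sd} (30), \code{floor} (5), all in 10^3 platelets per uL;
#'   \code{background_rate} (measurements per person-year) and
#'   \code{p_dx_given_low} (probability a low value is accompanied by a
#'   thrombocytopenia diagnosis code).
#' @param under18_prob fraction of persons given an age below 18 (exercises
#'   the adult-only eligibility rule).
#'
#' @return an object of class \code{vsd_config}.
#' @seealso [generate_database()]
#' @export
sim_config <- function(n_persons = 20000L,
                       study_start_day = 0L,
                       study_end_day = 240L,
                       target_brand = "ChAdOx1-S",
                       comparator_brand = "BNT162b2",
                       rollout_days = c(0L, 150L),
                       assignment_intercept = -1.2,
                       assignment_coefficients = c(age = 0.3, sex_female = -0.2,
                                                   hypertension = 0.5,
                                                   diabetes = 0.4,
                                                   heart_failure = 0.3,
                                                   drug = 0.05),
                       covariate_spec = list(
                         age_mean = 52, age_sd = 16, age_min = 18, age_max = 99,
                         p_female = 0.55,
                         comorbidities = c(hypertension = 0.25, diabetes = 0.10,
                                           heart_failure = 0.04,
                                           vascular_disease = 0.06,
                                           stroke = 0.03, cancer = 0.06,
                                           renal_disease = 0.03),
                         utilisation_means = c(drug = 3, procedure = 1.2,
                                               measurement = 2),
                         history_mean_days = 1500, p_short_history = 0.05),
                       outcome_spec = data.frame(
                         name = "thrombocytopenia",
                         baseline_rate = 5 / 1000,
                         true_rr = 1,
                         stringsAsFactors = FALSE),
                       outcome_coefficients = c(age = 0.4, hypertension = 0.3,
                                                heart_failure = 0.3),
                       n_negative_controls = 30L,
                       nc_baseline_rate = 20 / 1000,
                       systematic_error = NULL,
                       censoring = list(disenrol_hazard = 0.05,
                                        death_hazard = 0.01),
                       dose2 = list(prob = 0.9, gap_mean = 70, gap_min = 19),
                       crossover_prob = 0,
                       short_gap_prob = 0,
                       platelet_spec = list(p_measured_near_event = 0.8,
                                            p_low_near_event = 0.3,
                                            normal_mean = 250, normal_sd = 50,
                                            low_mean = 90, low_sd = 30,
                                            floor = 5,
                                            background_rate = 0.3,
                                            p_dx_given_low = 0.5),
                       under18_prob = 0) {
  cfg <- list(n_persons = as.integer(n_persons),
              study_start_day = as.integer(study_start_day),
              study_end_day = as.integer(study_end_day),
              target_brand = target_brand,
              comparator_brand = comparator_brand,
              rollout_days = as.integer(rollout_days),
              assignment_intercept = assignment_intercept,
              assignment_coefficients = assignment_coefficients,
              covariate_spec = covariate_spec,
              outcome_spec = outcome_spec,
              outcome_coefficients = outcome_coefficients,
              n_negative_controls = as.integer(n_negative_controls),
              nc_baseline_rate = nc_baseline_rate,
              systematic_error = systematic_error,
              censoring = censoring,
              dose2 = dose2,
              crossover_prob = crossover_prob,
              short_gap_prob = short_gap_prob,
              platelet_spec = platelet_spec,
              under18_prob = under18_prob)
  class(cfg) <- "vsd_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_finite(cfg$n_persons, "n_persons")
  if (cfg$n_persons < 1)
    stopf("n_persons must be >= 1", class = "vaxsafety_config_error")
  if (cfg$study_end_day <= cfg$study_start_day)
    stopf("study_end_day must exceed study_start_day",
          class = "vaxsafety_config_error")
  assert_finite(cfg$assignment_intercept, "assignment_intercept")
  assert_finite(cfg$assignment_coefficients, "assignment_coefficients")
  assert_finite(cfg$outcome_coefficients, "outcome_coefficients")
  os <- cfg$outcome_spec
  if (!all(c("name", "baseline_rate", "true_rr") %in% names(os)))
    stopf("outcome_spec needs columns name, baseline_rate, true_rr",
          class = "vaxsafety_config_error")
  assert_finite(os$baseline_rate, "outcome_spec$baseline_rate")
  assert_finite(os$true_rr, "outcome_spec$true_rr")
  if (any(os$baseline_rate < 0))
    stopf("baseline rates must be non-negative",
          class = "vaxsafety_config_error")
  if (any(os$true_rr <= 0))
    stopf("true rate ratios must be > 0", class = "vaxsafety_config_error")
  cs <- cfg$covariate_spec
  assert_finite(cs$comorbidities, "comorbidity prevalences")
  if (length(cs$comorbidities) &&
      (any(cs$comorbidities < 0) || any(cs$comorbidities > 1)))
    stopf("comorbidity prevalences must lie in [0,1]",
          class = "vaxsafety_config_error")
  assert_finite(cs$utilisation_means, "utilisation means")
  assert_finite(cfg$nc_baseline_rate, "nc_baseline_rate")
  if (cfg$nc_baseline_rate < 0)
    stopf("nc_baseline_rate must be non-negative",
          class = "vaxsafety_config_error")
  if (!is.null(cfg$systematic_error)) {
    assert_finite(cfg$systematic_error$mean, "systematic_error$mean")
    assert_finite(cfg$systematic_error$sd, "systematic_error$sd")
    if (cfg$systematic_error$sd < 0)
      stopf("systematic_error$sd must be >= 0",
            class = "vaxsafety_config_error")
  }
  assert_finite(unlist(cfg$censoring), "censoring hazards")
  if (any(unlist(cfg$censoring) < 0))
    stopf("censoring hazards must be non-negative",
          class = "vaxsafety_config_error")
  for (p in c("crossover_prob", "short_gap_prob", "under18_prob")) {
    assert_finite(cfg[[p]], p)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stopf("%s must lie in [0,1]", p, class = "vaxsafety_config_error")
  }
  invisible(cfg)
}

#' @export
print.vsd_config <- function(x, ...) {
  cat("Synthetic vaccination database configuration\n")
  cat(sprintf("  persons: %d   study days: [%d, %d]\n", x$n_persons,
              x$study_start_day, x$study_end_day))
  cat(sprintf("  arms: %s (target) vs %s (comparator)\n",
              x$target_brand, x$comparator_brand))
  cat(sprintf("  outcomes: %d (+%d negative controls)\n",
              nrow(x$outcome_spec), x$n_negative_controls))
  if (!is.null(x$systematic_error))
    cat(sprintf("  injected systematic error: N(%.3f, %.3f) on log-RR scale\n",
                x$systematic_error$mean, x$systematic_error$sd))
  invisible(x)
}

# Per-person covariate values used by both the assignment and the outcome
# models. Age enters as (age - 50)/10.
covariate_values <- function(persons, flags, util_counts) {
  vals <- list(age = (persons$age - 50) / 10,
               sex_female = as.numeric(persons$sex == "female"))
  for (nm in colnames(flags)) vals[[nm]] <- flags[, nm]
  for (nm in colnames(util_counts)) vals[[nm]] <- util_counts[, nm]
  vals
}

linear_predictor <- function(values, intercept, coefficients) {
  lp <- rep(intercept, length(values$age))
  for (nm in names(coefficients)) {
    v <- values[[nm]]
    if (is.null(v))
      stopf("unknown covariate '%s' in coefficient vector", nm,
            class = "vaxsafety_config_error")
    lp <- lp + coefficients[[nm]] * v
  }
  lp
}

#' Generate a synthetic vaccination database
#'
#' Draws a complete synthetic database (persons, vaccinations, clinical
#' events, platelet measurements) plus the generating ground truth, under
#' the configuration in \code{config}. Deterministic for a fixed
#' \code{(config, seed)} pair.
#'
#' Confounding arises because the same covariates appear in the brand
#' assignment model and (log-linearly) in every outcome hazard. Negative
#' controls always have true rate ratio 1. When
#' \code{config$systematic_error} is set, each outcome (negative controls
#' included) receives a multiplicative ascertainment bias in the target
#' arm, drawn once per outcome from the configured normal distribution on
#' the log scale.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return an object of class \code{vsd_database}: a list with data.frames
#'   \code{person}, \code{vaccination}, \code{event}, \code{measurement}
#'   and a \code{ground_truth} list (\code{outcomes} data.frame with the
#'   true rate ratio and injected log bias per outcome; \code{assignment}
#'   data.frame with each person's true target-assignment probability).
#' @export
generate_database <- function(config, seed = 1L) {
  validate_sim_config(config)
  with_seed(seed, generate_database_impl(config))
}

generate_database_impl <- function(cfg) {
  n <- cfg$n_persons
  cs <- cfg$covariate_spec
  epoch <- 2021L

  ## persons -----------------------------------------------------------
  age <- round(pmin(cs$age_max, pmax(cs$age_min,
                                     stats::rnorm(n, cs$age_mean, cs$age_sd))))
  if (cfg$under18_prob > 0) {
    juv <- stats::runif(n) < cfg$under18_prob
    age[juv] <- sample(12:17, sum(juv), replace = TRUE)
  }
  sex <- ifelse(stats::runif(n) < cs$p_female, "female", "male")
  history <- ifelse(stats::runif(n) < (cs$p_short_history %||% 0),
                    sample(30:364, n, replace = TRUE),
                    365L + stats::rpois(n, max(0, cs$history_mean_days - 365)))
  obs_start <- cfg$study_start_day - as.integer(history)

  vax_day <- sample(seq(cfg$rollout_days[1], cfg$rollout_days[2]), n,
                    replace = TRUE)

  t_dis <- vax_day +
    floor(stats::rexp(n, rate = pmax(cfg$censoring$disenrol_hazard, 1e-12)) *
            365.25)
  t_death <- vax_day +
    floor(stats::rexp(n, rate = pmax(cfg$censoring$death_hazard, 1e-12)) *
            365.25)
  obs_end <- pmin(cfg$study_end_day, t_dis, t_death)
  death_day <- ifelse(t_death <= pmin(cfg$study_end_day, t_dis), t_death,
                      NA_integer_)

  persons <- data.frame(person_id = seq_len(n),
                        sex = sex,
                        birth_year = epoch - as.integer(age),
                        observation_start_day = as.integer(obs_start),
                        observation_end_day = as.integer(obs_end),
                        death_day = as.integer(death_day),
                        stringsAsFactors = FALSE)
  persons$age <- as.integer(age)  # internal convenience, dropped on write

  ## baseline covariates ------------------------------------------------
  com_names <- names(cs$comorbidities)
  flags <- matrix(0, n, length(com_names), dimnames = list(NULL, com_names))
  for (nm in com_names)
    flags[, nm] <- stats::rbinom(n, 1, cs$comorbidities[[nm]])

  util_names <- names(cs$utilisation_means)
  util_recent <- matrix(0L, n, length(util_names),
                        dimnames = list(NULL, util_names))
  util_old <- matrix(0L, n, length(util_names),
                     dimnames = list(NULL, util_names))
  for (nm in util_names) {
    util_recent[, nm] <- stats::rpois(n, cs$utilisation_means[[nm]])
    util_old[, nm] <- stats::rpois(n, cs$utilisation_means[[nm]] / 2)
  }

  vals <- covariate_values(persons, flags, util_recent)

  ## brand assignment ----------------------------------------------------
  p_target <- stats::plogis(linear_predictor(vals, cfg$assignment_intercept,
                                             cfg$assignment_coefficients))
  is_target <- stats::runif(n) < p_target
  brand1 <- ifelse(is_target, cfg$target_brand, cfg$comparator_brand)

  vaccinated <- vax_day <= obs_end & vax_day >= obs_start
  vax <- data.frame(person_id = persons$person_id[vaccinated],
                    brand = brand1[vaccinated],
                    dose_number = 1L,
                    day = as.integer(vax_day[vaccinated]),
                    stringsAsFactors = FALSE)

  has_d2 <- vaccinated & stats::runif(n) < cfg$dose2$prob
  gap <- cfg$dose2$gap_min +
    stats::rpois(n, max(0, cfg$dose2$gap_mean - cfg$dose2$gap_min))
  short <- stats::runif(n) < cfg$short_gap_prob
  gap[short] <- sample(1:14, sum(short), replace = TRUE)
  d2_day <- vax_day + gap
  has_d2 <- has_d2 & d2_day <= obs_end
  cross <- stats::runif(n) < cfg$crossover_prob
  brand2 <- ifelse(cross,
                   ifelse(is_target, cfg$comparator_brand, cfg$target_brand),
                   brand1)
  if (any(has_d2))
    vax <- rbind(vax, data.frame(person_id = persons$person_id[has_d2],
                                 brand = brand2[has_d2],
                                 dose_number = 2L,
                                 day = as.integer(d2_day[has_d2]),
                                 stringsAsFactors = FALSE))
  vax <- vax[order(vax$person_id, vax$dose_number), , drop = FALSE]
  rownames(vax) <- NULL

  ## clinical events -----------------------------------------------------
  ev_pid <- integer(0); ev_concept <- character(0); ev_day <- integer(0)
  add_events <- function(pid, concept, day) {
    ev_pid <<- c(ev_pid, pid)
    ev_concept <<- c(ev_concept, rep(concept, length(pid)))
    ev_day <<- c(ev_day, as.integer(day))
  }

  # comorbidity condition records strictly before vaccination
  for (nm in com_names) {
    idx <- which(flags[, nm] == 1)
    if (!length(idx)) next
    hi <- pmin(vax_day[idx] - 1L, obs_end[idx])
    lo <- obs_start[idx]
    day <- lo + floor(stats::runif(length(idx)) * pmax(1, hi - lo + 1))
    add_events(persons$person_id[idx], nm, pmin(day, hi))
  }

  # utilisation records: recent counts in the 180 days before vaccination,
  # older counts before that window
  for (nm in util_names) {
    cnt <- util_recent[, nm]
    idx <- rep.int(seq_len(n), cnt)
    if (length(idx)) {
      lo <- pmax(obs_start[idx], vax_day[idx] - 180L)
      day <- lo + floor(stats::runif(length(idx)) *
                          pmax(1, vax_day[idx] - lo))
      add_events(persons$person_id[idx], nm,
                 pmin(day, vax_day[idx] - 1L))
    }
    cnt <- util_old[, nm]
    ok <- obs_start < vax_day - 181L
    cnt[!ok] <- 0L
    idx <- rep.int(seq_len(n), cnt)
    if (length(idx)) {
      lo <- obs_start[idx]
      hi <- vax_day[idx] - 181L
      day <- lo + floor(stats::runif(length(idx)) * pmax(1, hi - lo + 1))
      add_events(persons$person_id[idx], nm, pmin(day, hi))
    }
  }

  ## outcome + negative control events ----------------------------------
  outcomes <- cfg$outcome_spec
  nc_names <- if (cfg$n_negative_controls > 0)
    sprintf("nc_%03d", seq_len(cfg$n_negative_controls)) else character(0)
  all_out <- data.frame(
    outcome = c(outcomes$name, nc_names),
    baseline_rate = c(outcomes$baseline_rate,
                      rep(cfg$nc_baseline_rate, length(nc_names))),
    true_rr = c(outcomes$true_rr, rep(1, length(nc_names))),
    negative_control = c(rep(FALSE, nrow(outcomes)),
                         rep(TRUE, length(nc_names))),
    stringsAsFactors = FALSE)
  if (!is.null(cfg$systematic_error)) {
    all_out$bias_log <- stats::rnorm(nrow(all_out),
                                     cfg$systematic_error$mean,
                                     cfg$systematic_error$sd)
  } else all_out$bias_log <- 0

  cov_mult <- exp(linear_predictor(vals, 0, cfg$outcome_coefficients))
  years <- pmax(0, obs_end - obs_start) / 365.25
  thrombo_pid <- integer(0); thrombo_day <- integer(0)
  for (k in seq_len(nrow(all_out))) {
    rate <- all_out$baseline_rate[k] * cov_mult *
      ifelse(is_target, all_out$true_rr[k] * exp(all_out$bias_log[k]), 1)
    cnt <- stats::rpois(n, rate * years)
    idx <- rep.int(seq_len(n), cnt)
    if (!length(idx)) next
    day <- obs_start[idx] +
      floor(stats::runif(length(idx)) * pmax(1, obs_end[idx] - obs_start[idx] + 1))
    day <- pmin(day, obs_end[idx])
    add_events(persons$person_id[idx], all_out$outcome[k], day)
    if (!all_out$negative_control[k]) {
      thrombo_pid <- c(thrombo_pid, persons$person_id[idx])
      thrombo_day <- c(thrombo_day, as.integer(day))
    }
  }

  events <- data.frame(person_id = ev_pid, concept = ev_concept,
                       day = ev_day, stringsAsFactors = FALSE)
  events <- events[order(events$person_id, events$day, events$concept), ,
                   drop = FALSE]
  rownames(events) <- NULL

  ## platelet measurements ----------------------------------------------
  ps <- cfg$platelet_spec
  m_pid <- integer(0); m_day <- integer(0); m_val <- numeric(0)
  if (length(thrombo_pid)) {
    take <- stats::runif(length(thrombo_pid)) < ps$p_measured_near_event
    if (any(take)) {
      pid <- thrombo_pid[take]
      pobs_end <- obs_end[pid]; pobs_start <- obs_start[pid]
      day <- thrombo_day[take] + sample(-3:3, sum(take), replace = TRUE)
      day <- pmin(pmax(day, pobs_start), pobs_end)
      low <- stats::runif(length(pid)) < ps$p_low_near_event
      val <- ifelse(low,
                    pmax(ps$floor, stats::rnorm(length(pid), ps$low_mean,
                                                ps$low_sd)),
                    pmax(ps$floor, stats::rnorm(length(pid), ps$normal_mean,
                                                ps$normal_sd)))
      m_pid <- c(m_pid, pid); m_day <- c(m_day, as.integer(day))
      m_val <- c(m_val, round(val, 1))
      dx <- low & stats::runif(length(pid)) < ps$p_dx_given_low
      if (any(dx)) {
        events <- rbind(events,
                        data.frame(person_id = pid[dx],
                                   concept = "thrombocytopenia_dx",
                                   day = as.integer(day[dx]),
                                   stringsAsFactors = FALSE))
      }
    }
  }
  bg_cnt <- stats::rpois(n, (ps$background_rate %||% 0) * years)
  idx <- rep.int(seq_len(n), bg_cnt)
  if (length(idx)) {
    day <- obs_start[idx] +
      floor(stats::runif(length(idx)) * pmax(1, obs_end[idx] - obs_start[idx] + 1))
    val <- pmax(ps$floor, stats::rnorm(length(idx), ps$normal_mean,
                                       ps$normal_sd))
    m_pid <- c(m_pid, persons$person_id[idx])
    m_day <- c(m_day, as.integer(pmin(day, obs_end[idx])))
    m_val <- c(m_val, round(val, 1))
  }
  measurements <- data.frame(person_id = m_pid, day = m_day, value = m_val,
                             stringsAsFactors = FALSE)
  measurements <- measurements[order(measurements$person_id,
                                     measurements$day), , drop = FALSE]
  rownames(measurements) <- NULL
  events <- events[order(events$person_id, events$day, events$concept), ,
                   drop = FALSE]
  rownames(events) <- NULL

  db <- list(person = persons,
             vaccination = vax,
             event = events,
             measurement = measurements,
             ground_truth = list(
               outcomes = all_out,
               assignment = data.frame(person_id = persons$person_id,
                                       p_target = p_target)),
             config = cfg)
  class(db) <- "vsd_database"
  db
}

#' @export
print.vsd_database <- function(x, ...) {
  cat("Synthetic vaccination database\n")
  cat(sprintf("  %d persons, %d vaccination records, %d events, %d platelet measurements\n",
              nrow(x$person), nrow(x$vaccination), nrow(x$event),
              nrow(x$measurement)))
  gt <- x$ground_truth$outcomes
  cat(sprintf("  outcomes: %d of interest, %d negative controls\n",
              sum(!gt$negative_control), sum(gt$negative_control)))
  invisible(x)
}

#' List negative-control outcome concepts of a synthetic database
#' @param db a \code{vsd_database}.
#' @return character vector of concept names.
#' @export
negative_control_concepts <- function(db) {
  gt <- db$ground_truth$outcomes
  gt$outcome[gt$negative_control]
}

#' Read a simulation configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [sim_config()];
#' \code{outcome_spec} is a list of \code{{name, baseline_rate, true_rr}}
#' entries.
#'
#' @param path YAML file path.
#' @return a \code{vsd_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$outcome_spec))
    raw$outcome_spec <- do.call(rbind, lapply(raw$outcome_spec, function(o)
      data.frame(name = o$name, baseline_rate = o$baseline_rate,
                 true_rr = o$true_rr, stringsAsFactors = FALSE)))
  for (nm in c("assignment_coefficients", "outcome_coefficients"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$covariate_spec)) {
    cs <- raw$covariate_spec
    for (nm in c("comorbidities", "utilisation_means"))
      if (!is.null(cs[[nm]])) cs[[nm]] <- unlist(cs[[nm]])
    defaults <- formals(sim_config)$covariate_spec
    raw$covariate_spec <- utils::modifyList(eval(defaults), cs)
  }
  do.call(sim_config, raw)
}
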