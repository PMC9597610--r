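#' Study configuration
#'
#' Describes a full comparative-safety study: the databases, the
#' target/comparator brand-dose comparisons, the outcome registry, the
#' TTS variants, the diagnostic thresholds and the seeds.
#'
#' @param databases named list; each element a \code{vsd_database} or a
#'   directory path readable by [read_database()].
#' @param comparisons list of comparisons; each
#'   \code{list(name =, target = list(brand =, dose =), comparator =
#'   list(brand =, dose =))}.
#' @param outcomes outcome registry (named list of
#'   [outcome_definition()]); \code{NULL} derives one per database from
#'   its ground truth.
#' @param tts_variants named list of [tts_definition()] objects analysed
#'   as additional outcomes (default none).
#' @param eligibility an [eligibility_rules()] object.
#' @param risk_window_days at-risk window (default 28).
#' @param thresholds list: \code{smd} (0.1), \code{mdrr} (5),
#'   \code{nc_fraction} (0.20), \code{alpha} (0.05), \code{power} (0.80).
#' @param subsample named numeric vector of per-database sampling
#'   fractions (applied after eligibility filtering).
#' @param stratify logical; add age-band-by-sex stratified estimates for
#'   reported outcomes.
#' @param ps list of propensity-model settings: \code{folds},
#'   \code{lambda_grid}.
#' @param match list of matching settings: \code{caliper_sd} (0.2),
#'   \code{max_ratio} (4).
#' @param min_negative_controls minimum usable negative controls for the
#'   empirical null (default 5).
#' @param seed master seed; stage seeds are derived per (database,
#'   comparison, stage) with [derive_seed()].
#' @return an object of class \code{study_config}.
#' @export
study_config <- function(databases, comparisons, outcomes = NULL,
                         tts_variants = NULL,
                         eligibility = eligibility_rules(),
                         risk_window_days = 28L,
                         thresholds = list(smd = 0.1, mdrr = 5,
                                           nc_fraction = 0.20,
                                           alpha = 0.05, power = 0.80),
                         subsample = NULL, stratify = FALSE,
                         ps = list(folds = 10L, lambda_grid = NULL),
                         match = list(caliper_sd = 0.2, max_ratio = 4L),
                         min_negative_controls = 5L,
                         seed = 1L) {
  if (is.null(names(databases)) || any(names(databases) == ""))
    stopf("databases must be a named list", class = "vaxsafety_config_error")
  thr <- utils::modifyList(list(smd = 0.1, mdrr = 5, nc_fraction = 0.20,
                                alpha = 0.05, power = 0.80), thresholds)
  if (any(unlist(thr) <= 0))
    stopf("diagnostic thresholds must be positive",
          class = "vaxsafety_config_error")
  for (cmp in comparisons) {
    if (is.null(cmp$target$brand) || is.null(cmp$comparator$brand))
      stopf("each comparison needs target and comparator brand+dose",
            class = "vaxsafety_config_error")
  }
  structure(list(databases = databases, comparisons = comparisons,
                 outcomes = outcomes, tts_variants = tts_variants,
                 eligibility = eligibility,
                 risk_window_days = as.integer(risk_window_days),
                 thresholds = thr, subsample = subsample,
                 stratify = stratify, ps = ps,
                 match = utils::modifyList(list(caliper_sd = 0.2,
                                                max_ratio = 4L), match),
                 min_negative_controls = min_negative_controls,
                 seed = as.integer(seed)),
            class = "study_config")
}

# fast event lookups: one (person_id, day) frame per concept
index_events <- function(db) {
  split(db$event[c("person_id", "day")], db$event$concept)
}

concept_events <- function(ev_index, concepts) {
  subs <- ev_index[intersect(concepts, names(ev_index))]
  if (!length(subs))
    return(data.frame(person_id = integer(0), day = integer(0)))
  do.call(rbind, unname(subs))
}

# first event day per cohort entry inside (index, follow_up_end]
first_event_days <- function(sub, cohort) {
  out <- rep(NA_integer_, nrow(cohort))
  if (!nrow(sub) || !nrow(cohort)) return(out)
  idx <- match(sub$person_id, cohort$person_id)
  ok <- !is.na(idx) & sub$day > cohort$index_day[idx] &
    sub$day <= cohort$follow_up_end_day[idx]
  if (!any(ok)) return(out)
  agg <- tapply(sub$day[ok], idx[ok], min)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

# drop entries with a member event strictly before index
exclude_prior_from_sub <- function(sub, cohort) {
  if (!nrow(sub) || !nrow(cohort)) return(cohort)
  idx <- match(sub$person_id, cohort$person_id)
  prior <- !is.na(idx) & sub$day < cohort$index_day[idx]
  drop <- unique(idx[prior])
  if (!length(drop)) return(cohort)
  out <- cohort[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# first TTS event day per cohort entry: earliest in-window thromboembolic
# event with a thrombocytopenia day inside the concurrency window
first_tts_days <- function(db, ev_index, cohort, tts, registry) {
  concepts <- resolve_concepts(tts$thrombo_outcome, registry)
  sub <- concept_events(ev_index, concepts)
  out <- rep(NA_integer_, nrow(cohort))
  if (!nrow(sub) || !nrow(cohort)) return(out)
  idx <- match(sub$person_id, cohort$person_id)
  ok <- !is.na(idx) & sub$day > cohort$index_day[idx] &
    sub$day <= cohort$follow_up_end_day[idx]
  sub <- sub[ok, , drop = FALSE]; idx <- idx[ok]
  if (!nrow(sub)) return(out)
  dx <- concept_events(ev_index, tts$dx_concept)
  mm <- db$measurement
  low <- mm[mm$value < tts$platelet_threshold, c("person_id", "day")]
  tdays <- rbind(dx, low)
  ord <- order(idx, sub$day)
  sub <- sub[ord, , drop = FALSE]; idx <- idx[ord]
  for (j in seq_len(nrow(sub))) {
    i <- idx[j]
    if (!is.na(out[i])) next
    td <- tdays$day[tdays$person_id == sub$person_id[j]]
    if (classify_tts(sub$day[j], td, tts)) out[i] <- sub$day[j]
  }
  out
}

# one analysable outcome: a registry outcome or a TTS variant
analysis_units <- function(registry, tts_variants) {
  units <- list()
  for (nm in names(registry)) {
    if (registry[[nm]]$negative_control) next
    units[[nm]] <- list(name = nm, kind = "outcome", outcome = nm)
  }
  for (nm in names(tts_variants %||% list()))
    units[[nm]] <- list(name = nm, kind = "tts", tts = tts_variants[[nm]])
  units
}

#' Run a full comparative-safety study
#'
#' Per (database, comparison): builds the target and comparator cohorts,
#' fits the propensity model, matches, and applies the covariate-balance
#' gate — a failure skips all estimation for that comparison. Per outcome
#' it then excludes prior history, re-matches, ascertains first events,
#' and estimates rates, IRR, IRD, ARD and MDRR; an MDRR above the
#' threshold suppresses the database-specific estimate (the estimate
#' still feeds the meta-analysis). Negative controls are analysed
#' identically; the empirical null is fitted from them, the residual-bias
#' diagnostic is applied (failure marks the analysis calibrated-only),
#' and every estimable estimate is calibrated. Finally, estimates are
#' pooled across the balance-passing databases per comparison with
#' [dl_meta()] and the pooled estimates are calibrated against pooled
#' negative controls. Deterministic under the configuration seed.
#'
#' Any stage error is logged with its (database, comparison, outcome)
#' context and quarantines that cell, not the run.
#'
#' @param config a [study_config()].
#' @return an object of class \code{vaxsafety_study} with data.frames
#'   \code{estimates}, \code{meta}, \code{diagnostics}, \code{balance},
#'   \code{negative_controls}, optional \code{stratified}, a list
#'   \code{matches}, and a character \code{log}.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  thr <- config$thresholds
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  estimates <- list(); balance_rows <- list(); diag_rows <- list()
  nc_rows <- list(); match_sets <- list(); strat_rows <- list()
  db_results <- list()  # for meta: [[comparison]][[database]]

  for (db_name in names(config$databases)) {
    db <- config$databases[[db_name]]
    if (is.character(db)) db <- read_database(db)
    registry <- config$outcomes %||% registry_from_database(db)
    units <- analysis_units(registry, config$tts_variants)
    nc_names <- names(registry)[vapply(registry, `[[`, TRUE,
                                       "negative_control")]
    ev_index <- index_events(db)
    concept_cache <- lapply(registry, function(o)
      concept_events(ev_index, resolve_concepts(o, registry)))

    for (cmp in config$comparisons) {
      cmp_name <- cmp$name %||%
        sprintf("%s_d%d_vs_%s_d%d", cmp$target$brand, cmp$target$dose,
                cmp$comparator$brand, cmp$comparator$dose)
      cell_ctx <- sprintf("[%s/%s]", db_name, cmp_name)
      res <- tryCatch(
        run_comparison(db, db_name, cmp, cmp_name, config, registry,
                       units, nc_names, ev_index, concept_cache, note),
        error = function(e) {
          note("%s quarantined: %s", cell_ctx, conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      estimates <- c(estimates, res$estimates)
      balance_rows <- c(balance_rows, list(res$balance))
      diag_rows <- c(diag_rows, list(res$diagnostics))
      nc_rows <- c(nc_rows, res$nc_rows)
      match_sets[[paste(db_name, cmp_name, sep = "/")]] <- res$matches
      strat_rows <- c(strat_rows, res$stratified)
      db_results[[cmp_name]][[db_name]] <- res$for_meta
    }
  }

  estimates_df <- do.call(rbind, estimates)
  rownames(estimates_df) <- NULL
  balance_df <- do.call(rbind, balance_rows)
  diagnostics_df <- do.call(rbind, diag_rows)
  nc_df <- do.call(rbind, nc_rows)
  stratified_df <- if (length(strat_rows)) do.call(rbind, strat_rows)

  meta_df <- build_meta(db_results, config, note)

  structure(list(estimates = estimates_df,
                 meta = meta_df,
                 diagnostics = diagnostics_df,
                 balance = balance_df,
                 negative_controls = nc_df,
                 stratified = stratified_df,
                 matches = match_sets,
                 log = log_lines,
                 config = config),
            class = "vaxsafety_study")
}

run_comparison <- function(db, db_name, cmp, cmp_name, config, registry,
                           units, nc_names, ev_index, concept_cache, note) {
  thr <- config$thresholds
  seed_of <- function(stage, ...)
    derive_seed(config$seed, db_name, cmp_name, stage, ...)

  coh_t <- build_cohort(db, cmp$target$brand, cmp$target$dose,
                        config$eligibility, config$risk_window_days,
                        arm = "target")
  coh_c <- build_cohort(db, cmp$comparator$brand, cmp$comparator$dose,
                        config$eligibility, config$risk_window_days,
                        arm = "comparator")
  frac <- config$subsample[[db_name]] %||% 1
  if (frac < 1) {
    coh_t <- subsample_cohort(coh_t, frac, seed_of("subsample", "t"))
    coh_c <- subsample_cohort(coh_c, frac, seed_of("subsample", "c"))
  }
  if (nrow(coh_t) < 2 || nrow(coh_c) < 2)
    stopf("cohort too small (target %d, comparator %d)", nrow(coh_t),
          nrow(coh_c), class = "vaxsafety_input_error")

  scores <- list(charlson_romano_definition(), chads_vasc_definition())
  cov_t <- extract_covariates(db, coh_t, score_definitions = scores)
  cov_c <- extract_covariates(db, coh_c, score_definitions = scores)
  cov <- rbind_covariates(cov_t, cov_c)
  arm <- c(rep("target", nrow(coh_t)), rep("comparator", nrow(coh_c)))

  model <- fit_propensity_model(cov, arm,
                                lambda_grid = config$ps$lambda_grid,
                                folds = config$ps$folds %||% 10L,
                                seed = seed_of("ps"))
  logit_all <- predict_logit(model, cov)
  logit_t <- stats::setNames(logit_all[arm == "target"], coh_t$person_id)
  logit_c <- stats::setNames(logit_all[arm == "comparator"],
                             coh_c$person_id)

  ms <- greedy_match(logit_t, logit_c,
                     id_target = coh_t$person_id,
                     id_comparator = coh_c$person_id,
                     caliper_sd = config$match$caliper_sd,
                     max_ratio = config$match$max_ratio,
                     seed = seed_of("match"))
  mp <- matched_persons(ms)
  smd_pre <- compute_smd(cov, coh_t$person_id, coh_c$person_id)
  smd_post <- compute_smd(cov, mp$target, mp$comparator)
  bal <- balance_table(smd_pre, smd_post)
  gate <- balance_gate(bal, thr$smd)
  note("[%s/%s] balance gate: %s (max |SMD| = %.3f)", db_name, cmp_name,
       if (gate$pass) "pass" else "fail", gate$max_abs_smd)
  bal_out <- cbind(database = db_name, comparison = cmp_name, bal)

  all_units <- c(units, lapply(nc_names, function(nm)
    list(name = nm, kind = "nc", outcome = nm)))
  names(all_units) <- vapply(all_units, `[[`, "", "name")

  estimates <- list(); nc_rows <- list(); strat_rows <- list()
  nc_effects <- list(); unit_results <- list()
  null_dist <- NULL; ncd <- list(fraction = NA_real_, pass = NA,
                                 evaluable = FALSE)

  if (gate$pass) {
    for (u in all_units) {
      unit_results[[u$name]] <- tryCatch(
        analyse_unit(db, u, registry, concept_cache, ev_index, coh_t,
                     coh_c, logit_t, logit_c, config,
                     seed_of("match", u$name)),
        error = function(e) {
          note("[%s/%s/%s] quarantined: %s", db_name, cmp_name, u$name,
               conditionMessage(e))
          NULL
        })
    }
    nc_effects <- lapply(unit_results[nc_names], function(r)
      if (is.null(r)) NULL else r$est$irr)
    nc_effects <- Filter(Negate(is.null), nc_effects)
    null_dist <- tryCatch(
      fit_null(vapply(nc_effects, `[[`, 0, "log_rr"),
               vapply(nc_effects, `[[`, 0, "se"),
               min_controls = config$min_negative_controls),
      error = function(e) {
        note("[%s/%s] empirical calibration unavailable: %s", db_name,
             cmp_name, conditionMessage(e))
        NULL
      })
    ncd <- nc_diagnostic(nc_effects, thr$nc_fraction)
    if (isTRUE(ncd$evaluable))
      note("[%s/%s] negative-control diagnostic: %s (%.0f%% significant)",
           db_name, cmp_name, if (isTRUE(ncd$pass)) "pass" else "fail",
           100 * ncd$fraction)
  }

  calibrated_only <- isTRUE(ncd$evaluable) && !isTRUE(ncd$pass)

  for (u in all_units) {
    r <- unit_results[[u$name]]
    is_nc <- u$kind == "nc"
    if (!gate$pass) {
      status <- "skipped-balance"
      row <- estimate_row(db_name, cmp_name, u$name, is_nc, NULL, NULL,
                          status, calibrated_only = FALSE)
    } else if (is.null(r)) {
      status <- "not-estimable"
      row <- estimate_row(db_name, cmp_name, u$name, is_nc, NULL, NULL,
                          status, calibrated_only)
    } else {
      cal <- if (!is.null(null_dist)) calibrate(r$est$irr, null_dist)
      status <- if (!r$est$irr$estimable) "not-estimable"
        else if (!r$est$power$pass) "suppressed-power"
        else "reported"
      row <- estimate_row(db_name, cmp_name, u$name, is_nc, r, cal,
                          status, calibrated_only)
      if (config$stratify && status == "reported" && !is_nc) {
        sdat <- r$strat_data
        if (!is.null(sdat)) {
          sr <- stratified_estimates(sdat, thr$mdrr)
          strat_rows[[u$name]] <- cbind(database = db_name,
                                        comparison = cmp_name,
                                        outcome = u$name, sr)
        }
      }
    }
    if (is_nc) nc_rows[[u$name]] <- row else estimates[[u$name]] <- row
  }

  for_meta <- list(database = db_name, balance_pass = gate$pass,
                   units = lapply(unit_results[names(units)], function(r)
                     if (is.null(r)) NULL else r$est$irr),
                   ncs = nc_effects)

  diag <- data.frame(database = db_name, comparison = cmp_name,
                     balance_pass = gate$pass,
                     max_abs_smd = gate$max_abs_smd,
                     n_offending = length(gate$offending),
                     nc_fraction = ncd$fraction,
                     nc_pass = if (isTRUE(ncd$evaluable)) ncd$pass else NA,
                     calibration_available = !is.null(null_dist),
                     action = if (!gate$pass) "analysis skipped"
                       else if (calibrated_only) "calibrated-only"
                       else "reported",
                     stringsAsFactors = FALSE)

  list(estimates = estimates, balance = bal_out, diagnostics = diag,
       nc_rows = nc_rows, matches = ms, stratified = strat_rows,
       for_meta = for_meta)
}

analyse_unit <- function(db, unit, registry, concept_cache, ev_index,
                         coh_t, coh_c, logit_t, logit_c, config, seed) {
  if (unit$kind == "tts") {
    prior_sub <- concept_events(
      ev_index, resolve_concepts(unit$tts$thrombo_outcome, registry))
  } else {
    prior_sub <- concept_cache[[unit$outcome]]
  }
  ct <- exclude_prior_from_sub(prior_sub, coh_t)
  cc <- exclude_prior_from_sub(prior_sub, coh_c)
  if (nrow(ct) < 1 || nrow(cc) < 1)
    stopf("empty cohort after prior-history exclusion",
          class = "vaxsafety_input_error")
  ms <- greedy_match(logit_t[as.character(ct$person_id)],
                     logit_c[as.character(cc$person_id)],
                     id_target = ct$person_id,
                     id_comparator = cc$person_id,
                     caliper_sd = config$match$caliper_sd,
                     max_ratio = config$match$max_ratio,
                     seed = seed)
  mp <- matched_persons(ms)
  mt <- ct[ct$person_id %in% mp$target, , drop = FALSE]
  mc <- cc[cc$person_id %in% mp$comparator, , drop = FALSE]
  if (!nrow(mt) || !nrow(mc))
    stopf("no matched persons", class = "vaxsafety_input_error")

  if (unit$kind == "tts") {
    ev_t <- first_tts_days(db, ev_index, mt, unit$tts, registry)
    ev_c <- first_tts_days(db, ev_index, mc, unit$tts, registry)
  } else {
    ev_t <- first_event_days(prior_sub, mt)
    ev_c <- first_event_days(prior_sub, mc)
  }
  pt_t <- person_time(mt, ev_t)
  pt_c <- person_time(mc, ev_c)
  est <- estimate_comparison(sum(!is.na(ev_t)), sum(pt_t),
                             sum(!is.na(ev_c)), sum(pt_c),
                             config$risk_window_days)

  strat_data <- NULL
  if (config$stratify) {
    pm_t <- match(mt$person_id, db$person$person_id)
    pm_c <- match(mc$person_id, db$person$person_id)
    strat_data <- data.frame(
      arm = c(rep("target", nrow(mt)), rep("comparator", nrow(mc))),
      days = c(pt_t, pt_c) * 365.25,
      event = c(!is.na(ev_t), !is.na(ev_c)),
      age = c(day_to_year(mt$index_day) - db$person$birth_year[pm_t],
              day_to_year(mc$index_day) - db$person$birth_year[pm_c]),
      sex = c(db$person$sex[pm_t], db$person$sex[pm_c]),
      stringsAsFactors = FALSE)
  }
  list(est = est, n_target = nrow(mt), n_comparator = nrow(mc),
       strat_data = strat_data)
}

estimate_row <- function(db_name, cmp_name, outcome, is_nc, r, cal,
                         status, calibrated_only) {
  blank <- list(n_target = NA_integer_, n_comparator = NA_integer_,
                events_target = NA_real_, py_target = NA_real_,
                events_comparator = NA_real_, py_comparator = NA_real_,
                rate_target = NA_real_, rate_comparator = NA_real_,
                rr = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                p = NA_real_, ird_per_1000py = NA_real_,
                ard_per_100k = NA_real_, mdrr = NA_real_,
                cal_rr = NA_real_, cal_ci95_low = NA_real_,
                cal_ci95_high = NA_real_, cal_p = NA_real_)
  if (!is.null(r)) {
    e <- r$est
    blank$n_target <- r$n_target
    blank$n_comparator <- r$n_comparator
    blank$events_target <- e$irr$events_target
    blank$py_target <- e$irr$py_target
    blank$events_comparator <- e$irr$events_comparator
    blank$py_comparator <- e$irr$py_comparator
    blank$rate_target <- e$rate_target$rate_per_1000py
    blank$rate_comparator <- e$rate_comparator$rate_per_1000py
    blank$rr <- e$irr$rr
    blank$ci95_low <- e$irr$ci95_low
    blank$ci95_high <- e$irr$ci95_high
    blank$p <- e$irr$p
    blank$ird_per_1000py <- e$ird$ird_per_1000py
    blank$ard_per_100k <- e$ard$ard_per_100k
    blank$mdrr <- e$power$mdrr
    if (!is.null(cal) && cal$estimable) {
      blank$cal_rr <- cal$rr
      blank$cal_ci95_low <- cal$ci95_low
      blank$cal_ci95_high <- cal$ci95_high
      blank$cal_p <- cal$p
    }
  }
  cbind(data.frame(database = db_name, comparison = cmp_name,
                   outcome = outcome, negative_control = is_nc,
                   status = status, calibrated_only = calibrated_only,
                   stringsAsFactors = FALSE),
        as.data.frame(blank))
}

build_meta <- function(db_results, config, note) {
  rows <- list()
  for (cmp_name in names(db_results)) {
    per_db <- db_results[[cmp_name]]
    contributing <- inclusion_rule(per_db)
    if (!length(contributing)) {
      note("[%s] meta-analysis empty: no database passed the balance gate",
           cmp_name)
      next
    }
    per_db <- per_db[contributing]
    unit_names <- unique(unlist(lapply(per_db, function(r)
      names(r$units))))
    nc_ids <- unique(unlist(lapply(per_db, function(r) names(r$ncs))))
    nc_lists <- lapply(nc_ids, function(nc)
      Filter(Negate(is.null), lapply(per_db, function(r) r$ncs[[nc]])))
    names(nc_lists) <- nc_ids
    for (un in unit_names) {
      ests <- Filter(function(e) !is.null(e) && isTRUE(e$estimable),
                     lapply(per_db, function(r) r$units[[un]]))
      if (!length(ests)) next
      pc <- tryCatch(
        suppressWarnings(
          pooled_calibration(ests, nc_lists, labels = names(ests),
                             min_controls = config$min_negative_controls)),
        error = function(e) NULL)
      if (is.null(pc)) next
      pooled <- pc$pooled
      cal <- pc$calibrated
      rows[[paste(cmp_name, un)]] <- data.frame(
        comparison = cmp_name, outcome = un,
        k = pooled$k,
        databases = paste(sort(contributing), collapse = ";"),
        rr = pooled$rr, ci95_low = pooled$ci95_low,
        ci95_high = pooled$ci95_high, p = pooled$p,
        q = pooled$q, tau2 = pooled$tau2, i2 = pooled$i2,
        heterogeneity_warning = pooled$i2 > 60,
        cal_rr = if (!is.null(cal)) cal$rr else NA_real_,
        cal_ci95_low = if (!is.null(cal)) cal$ci95_low else NA_real_,
        cal_ci95_high = if (!is.null(cal)) cal$ci95_high else NA_real_,
        cal_p = if (!is.null(cal)) cal$p else NA_real_,
        calibration_available = pc$calibration_available,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.vaxsafety_study <- function(x, ...) {
  cat("Comparative vaccine-safety study\n")
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  %d (database, comparison) cells; %d passed the balance gate\n",
                nrow(x$diagnostics), sum(x$diagnostics$balance_pass)))
  }
  if (!is.null(x$estimates))
    cat(sprintf("  %d outcome estimates (%d reported)\n",
                nrow(x$estimates), sum(x$estimates$status == "reported")))
  if (!is.null(x$meta))
    cat(sprintf("  %d pooled (comparison, outcome) estimates\n",
                nrow(x$meta)))
  invisible(x)
}

#' @export
summary.vaxsafety_study <- function(object, ...) {
  rep_ <- object$estimates[object$estimates$status == "reported", ]
  cat("Reported database-specific estimates:\n")
  if (nrow(rep_))
    print(rep_[, c("database", "comparison", "outcome", "rr", "ci95_low",
                   "ci95_high", "cal_rr", "cal_ci95_low",
                   "cal_ci95_high")], digits = 3)
  if (!is.null(object$meta) && nrow(object$meta)) {
    cat("\nPooled estimates:\n")
    print(object$meta[, c("comparison", "outcome", "k", "rr", "cal_rr",
                          "cal_ci95_low", "cal_ci95_high", "i2")],
          digits = 3)
  }
  invisible(object)
}

#' Forest-style result table
#'
#' Database-specific and pooled rows per outcome, ordered by outcome,
#' then database alphabetically, with the pooled row last. Pooled rows
#' appear only where two or more databases contributed.
#'
#' @param study a [run_study()] result.
#' @return data.frame: \code{comparison}, \code{outcome}, \code{source},
#'   \code{rr}, \code{ci95_low}, \code{ci95_high}, \code{cal_rr},
#'   \code{cal_ci95_low}, \code{cal_ci95_high}.
#' @export
report_forest <- function(study) {
  cols <- c("comparison", "outcome", "source", "rr", "ci95_low",
            "ci95_high", "cal_rr", "cal_ci95_low", "cal_ci95_high")
  empty <- data.frame(comparison = character(0), outcome = character(0),
                      source = character(0), rr = numeric(0),
                      ci95_low = numeric(0), ci95_high = numeric(0),
                      cal_rr = numeric(0), cal_ci95_low = numeric(0),
                      cal_ci95_high = numeric(0), stringsAsFactors = FALSE)
  est <- study$estimates
  if (is.null(est) || !nrow(est)) return(empty)
  est <- est[est$status == "reported" & !est$negative_control, ]
  db_rows <- if (nrow(est)) data.frame(
    comparison = est$comparison, outcome = est$outcome,
    source = est$database, rr = est$rr, ci95_low = est$ci95_low,
    ci95_high = est$ci95_high, cal_rr = est$cal_rr,
    cal_ci95_low = est$cal_ci95_low, cal_ci95_high = est$cal_ci95_high,
    stringsAsFactors = FALSE) else empty
  meta <- study$meta
  pooled_rows <- if (!is.null(meta) && nrow(meta)) {
    m <- meta[meta$k >= 2, ]
    if (nrow(m)) data.frame(
      comparison = m$comparison, outcome = m$outcome, source = "pooled",
      rr = m$rr, ci95_low = m$ci95_low, ci95_high = m$ci95_high,
      cal_rr = m$cal_rr, cal_ci95_low = m$cal_ci95_low,
      cal_ci95_high = m$cal_ci95_high, stringsAsFactors = FALSE)
    else empty
  } else empty
  out <- rbind(db_rows, pooled_rows)
  pooled_last <- out$source == "pooled"
  out <- out[order(out$comparison, out$outcome, pooled_last,
                   out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write study results to a directory of CSV files
#'
#' Emits \code{estimates.csv}, \code{meta_estimates.csv},
#' \code{diagnostics.csv}, \code{balance.csv},
#' \code{negative_controls.csv}, \code{forest.csv}, per-comparison
#' \code{matches_*.csv}, \code{log.txt} and a run manifest
#' (\code{manifest.yaml}: seed, thresholds, package version).
#'
#' @param study a [run_study()] result.
#' @param directory output path.
#' @return the directory, invisibly.
#' @export
write_results <- function(study, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  wcsv <- function(df, name) {
    if (is.null(df))
      df <- data.frame()
    utils::write.csv(df, file.path(directory, name), row.names = FALSE)
  }
  wcsv(study$estimates, "estimates.csv")
  wcsv(study$meta, "meta_estimates.csv")
  wcsv(study$diagnostics, "diagnostics.csv")
  wcsv(study$balance, "balance.csv")
  wcsv(study$negative_controls, "negative_controls.csv")
  wcsv(report_forest(study), "forest.csv")
  if (!is.null(study$stratified)) wcsv(study$stratified, "stratified.csv")
  for (nm in names(study$matches)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    wcsv(as.data.frame(study$matches[[nm]]),
         sprintf("matches_%s.csv", safe))
  }
  writeLines(study$log, file.path(directory, "log.txt"))
  manifest <- list(seed = study$config$seed,
                   thresholds = study$config$thresholds,
                   risk_window_days = study$config$risk_window_days,
                   databases = names(study$config$databases),
                   package_version =
                     as.character(utils::packageVersion("vaxsafety")))
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(directory)
}
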