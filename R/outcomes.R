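#' Outcome definition
#'
#' An outcome is a named set of event concepts, or a composite of other
#' outcomes (its concept set is the union of the members'). Negative
#' controls are plain (non-composite) outcomes flagged as such.
#'
#' @param name outcome name.
#' @param concepts character vector of member event concepts (may be empty
#'   for composites).
#' @param composite_of optional character vector of other outcome names.
#' @param negative_control logical flag.
#' @return an object of class \code{outcome_definition}.
#' @export
outcome_definition <- function(name, concepts = character(0),
                               composite_of = NULL,
                               negative_control = FALSE) {
  if (negative_control && length(composite_of))
    stopf("a negative control outcome cannot be a composite",
          class = "vaxsafety_config_error")
  if (!length(concepts) && !length(composite_of))
    stopf("outcome '%s' needs at least one concept or composite member",
          name, class = "vaxsafety_config_error")
  structure(list(name = name, concepts = concepts,
                 composite_of = composite_of,
                 negative_control = negative_control),
            class = "outcome_definition")
}

#' Default thromboembolic outcome registry
#'
#' The study outcomes: deep vein thrombosis, pulmonary embolism, venous
#' thromboembolism (composite of the two), cerebral venous sinus
#' thrombosis, splanchnic/visceral vein thrombosis, ischaemic stroke,
#' myocardial infarction, intestinal infarction, arterial thromboembolism
#' (composite), and thrombocytopenia.
#'
#' @return a named list of [outcome_definition()] objects.
#' @export
default_outcome_registry <- function() {
  defs <- list(
    outcome_definition("deep_vein_thrombosis", "deep_vein_thrombosis"),
    outcome_definition("pulmonary_embolism", "pulmonary_embolism"),
    outcome_definition("venous_thromboembolism",
                       composite_of = c("deep_vein_thrombosis",
                                        "pulmonary_embolism")),
    outcome_definition("cerebral_venous_sinus_thrombosis",
                       "cerebral_venous_sinus_thrombosis"),
    outcome_definition("splanchnic_visceral_thrombosis",
                       "splanchnic_visceral_thrombosis"),
    outcome_definition("ischaemic_stroke", "ischaemic_stroke"),
    outcome_definition("myocardial_infarction", "myocardial_infarction"),
    outcome_definition("intestinal_infarction", "intestinal_infarction"),
    outcome_definition("arterial_thromboembolism",
                       composite_of = c("ischaemic_stroke",
                                        "myocardial_infarction",
                                        "intestinal_infarction")),
    outcome_definition("thrombocytopenia", "thrombocytopenia"))
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Build an outcome registry for a synthetic database
#'
#' One plain outcome per non-negative-control ground-truth outcome plus
#' one flagged definition per negative control.
#'
#' @param db a \code{vsd_database} carrying ground truth.
#' @return a named list of [outcome_definition()] objects.
#' @export
registry_from_database <- function(db) {
  gt <- db$ground_truth$outcomes
  defs <- lapply(seq_len(nrow(gt)), function(i)
    outcome_definition(gt$outcome[i], gt$outcome[i],
                       negative_control = gt$negative_control[i]))
  stats::setNames(defs, gt$outcome)
}

#' Read outcome definitions from a YAML file
#'
#' The file maps outcome names to entries with optional keys
#' \code{concepts}, \code{composite_of}, \code{negative_control}.
#'
#' @param path YAML file path.
#' @return a named list of [outcome_definition()] objects.
#' @export
read_outcome_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    outcome_definition(nm,
                       concepts = unlist(e$concepts) %||% character(0),
                       composite_of = unlist(e$composite_of),
                       negative_control = isTRUE(e$negative_control))
  })
  stats::setNames(defs, names(raw))
}

# All member concepts of an outcome, resolving composites recursively.
resolve_concepts <- function(outcome, registry, seen = character(0)) {
  if (is.character(outcome)) {
    if (!outcome %in% names(registry))
      stopf("unknown outcome name '%s'", outcome,
            class = "vaxsafety_input_error")
    outcome <- registry[[outcome]]
  }
  if (outcome$name %in% seen)
    stopf("cyclic composite definition at '%s'", outcome$name,
          class = "vaxsafety_config_error")
  concepts <- outcome$concepts
  for (member in outcome$composite_of) {
    if (!member %in% names(registry))
      stopf("composite member '%s' of '%s' is not defined", member,
            outcome$name, class = "vaxsafety_config_error")
    concepts <- c(concepts,
                  resolve_concepts(registry[[member]], registry,
                                   c(seen, outcome$name)))
  }
  unique(concepts)
}

#' First outcome event inside the risk window
#'
#' Returns the earliest member-concept event day in
#' \code{(index_day, follow_up_end_day]}, or \code{NA} when no event falls
#' inside the (possibly censored) window. Composites take the earliest day
#' across members.
#'
#' @param db a \code{vsd_database}.
#' @param entry one cohort entry (a one-row data.frame or a list with
#'   \code{person_id}, \code{index_day}, \code{follow_up_end_day}).
#' @param outcome an [outcome_definition()] or an outcome name resolved in
#'   \code{registry}.
#' @param registry outcome registry used to resolve composites.
#' @return integer day or \code{NA}.
#' @export
ascertain_first_event <- function(db, entry, outcome,
                                  registry = default_outcome_registry()) {
  concepts <- resolve_concepts(outcome, registry)
  ev <- db$event
  hit <- ev$person_id == entry$person_id & ev$concept %in% concepts &
    ev$day > entry$index_day & ev$day <= entry$follow_up_end_day
  if (!any(hit)) return(NA_integer_)
  min(ev$day[hit])
}

# Vectorised first-event ascertainment for a whole cohort (same window
# convention as ascertain_first_event).
first_events_for_cohort <- function(db, cohort, concepts) {
  ev <- db$event[db$event$concept %in% concepts, ]
  out <- rep(NA_integer_, nrow(cohort))
  if (!nrow(ev) || !nrow(cohort)) return(out)
  idx <- match(ev$person_id, cohort$person_id)
  ok <- !is.na(idx) & ev$day > cohort$index_day[idx] &
    ev$day <= cohort$follow_up_end_day[idx]
  if (!any(ok)) return(out)
  agg <- tapply(ev$day[ok], idx[ok], min)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

# Earliest member-concept event day per person over all history (used for
# prior-history exclusion).
first_any_event <- function(db, person_ids, concepts) {
  ev <- db$event[db$event$concept %in% concepts, ]
  out <- rep(NA_integer_, length(person_ids))
  if (!nrow(ev)) return(out)
  agg <- tapply(ev$day, ev$person_id, min)
  m <- match(as.character(person_ids), names(agg))
  out[!is.na(m)] <- as.integer(agg[m[!is.na(m)]])
  out
}

#' Exclude persons with a prior history of the outcome
#'
#' Removes cohort entries whose person has any member-concept event
#' strictly before their index day (all available history). Applied per
#' outcome, before propensity matching.
#'
#' @inheritParams ascertain_first_event
#' @param cohort a cohort data.frame.
#' @return the filtered cohort.
#' @export
exclude_prior_history <- function(cohort, db, outcome,
                                  registry = default_outcome_registry()) {
  if (!nrow(cohort)) return(cohort)
  concepts <- resolve_concepts(outcome, registry)
  first <- first_any_event(db, cohort$person_id, concepts)
  out <- cohort[is.na(first) | first >= cohort$index_day, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thrombosis-with-thrombocytopenia definition
#'
#' TTS is a thromboembolic event in the 28-day risk window with concurrent
#' thrombocytopenia — a diagnosis code or a platelet measurement below the
#' threshold — within \code{concurrency_window_days} before or after the
#' thromboembolic event. The main definition uses a 10-day window and a
#' threshold of 150 (10^3 platelets per uL); sensitivity variants use a
#' 5-day window or a threshold of 100. The thrombocytopenia day may fall
#' outside the 28-day risk window; only the thromboembolic event must be
#' inside it.
#'
#' @param thrombo_outcome name of the thromboembolic outcome.
#' @param concurrency_window_days days before/after the event (default 10).
#' @param platelet_threshold threshold in 10^3 platelets per uL, strict
#'   "<" (default 150).
#' @param dx_concept thrombocytopenia diagnosis concept.
#' @return an object of class \code{tts_definition}.
#' @export
tts_definition <- function(thrombo_outcome,
                           concurrency_window_days = 10L,
                           platelet_threshold = 150,
                           dx_concept = "thrombocytopenia_dx") {
  if (concurrency_window_days <= 0 || platelet_threshold <= 0)
    stopf("TTS window and threshold must be > 0",
          class = "vaxsafety_config_error")
  structure(list(thrombo_outcome = thrombo_outcome,
                 concurrency_window_days = as.integer(concurrency_window_days),
                 platelet_threshold = platelet_threshold,
                 dx_concept = dx_concept),
            class = "tts_definition")
}

#' Days with evidence of thrombocytopenia for one person
#'
#' The union of days carrying a thrombocytopenia diagnosis code and days
#' with a platelet measurement strictly below the threshold.
#'
#' @param db a \code{vsd_database}.
#' @param person_id person identifier.
#' @param platelet_threshold threshold in 10^3 platelets per uL.
#' @param dx_concept diagnosis concept name.
#' @return sorted integer vector of days (possibly empty).
#' @export
detect_thrombocytopenia_days <- function(db, person_id,
                                         platelet_threshold = 150,
                                         dx_concept = "thrombocytopenia_dx") {
  ev <- db$event
  dx_days <- ev$day[ev$person_id == person_id & ev$concept == dx_concept]
  mm <- db$measurement
  low_days <- mm$day[mm$person_id == person_id &
                       mm$value < platelet_threshold]
  sort(unique(c(dx_days, low_days)))
}

#' Classify a thromboembolic event as TTS
#'
#' @param thrombo_day day of the thromboembolic event (already inside the
#'   risk window).
#' @param thrombocytopenia_days integer vector of thrombocytopenia days,
#'   e.g. from [detect_thrombocytopenia_days()].
#' @param tts a [tts_definition()].
#' @return \code{TRUE} iff any thrombocytopenia day lies within
#'   \code{concurrency_window_days} of the event.
#' @export
classify_tts <- function(thrombo_day, thrombocytopenia_days, tts) {
  if (!length(thrombocytopenia_days)) return(FALSE)
  any(abs(thrombocytopenia_days - thrombo_day) <=
        tts$concurrency_window_days)
}

#' First TTS event for one cohort entry
#'
#' Scans the thromboembolic events of the entry's risk window in day order
#' and returns the first that qualifies as TTS under \code{tts}, or
#' \code{NA}.
#'
#' @inheritParams ascertain_first_event
#' @param tts a [tts_definition()].
#' @return integer day or \code{NA}.
#' @export
ascertain_first_tts <- function(db, entry, tts,
                                registry = default_outcome_registry()) {
  concepts <- resolve_concepts(tts$thrombo_outcome, registry)
  ev <- db$event
  hit <- ev$person_id == entry$person_id & ev$concept %in% concepts &
    ev$day > entry$index_day & ev$day <= entry$follow_up_end_day
  if (!any(hit)) return(NA_integer_)
  days <- sort(unique(ev$day[hit]))
  tdays <- detect_thrombocytopenia_days(db, entry$person_id,
                                        tts$platelet_threshold,
                                        tts$dx_concept)
  for (d in days) if (classify_tts(d, tdays, tts)) return(d)
  NA_integer_
}
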