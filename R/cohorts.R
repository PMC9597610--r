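#' Cohort eligibility rules
#'
#' Eligibility follows the active-comparator new-user design: adults only,
#' at least one year of database history before the index vaccination, a
#' recorded brand, complete age and sex, and exclusion of persons whose
#' second dose was recorded 14 days or less after the first (such gaps are
#' treated as data errors and the person is removed from both dose
#' cohorts).
#'
#' @param min_age_years minimum age at first dose (default 18).
#' @param min_prior_history_days minimum observed history before index
#'   (default 365).
#' @param min_dose_gap_days dose-1 to dose-2 gaps of this many days or
#'   fewer exclude the person (default 14).
#' @param require_known_brand drop records whose brand is "unknown".
#' @param require_complete_age_sex drop persons with missing age or sex.
#' @return an object of class \code{eligibility_rules}.
#' @export
eligibility_rules <- function(min_age_years = 18L,
                              min_prior_history_days = 365L,
                              min_dose_gap_days = 14L,
                              require_known_brand = TRUE,
                              require_complete_age_sex = TRUE) {
  thresholds <- c(min_age_years, min_prior_history_days, min_dose_gap_days)
  if (any(!is.finite(thresholds)) || any(thresholds < 0))
    stopf("eligibility thresholds must be non-negative",
          class = "vaxsafety_config_error")
  structure(list(min_age_years = min_age_years,
                 min_prior_history_days = min_prior_history_days,
                 min_dose_gap_days = min_dose_gap_days,
                 require_known_brand = require_known_brand,
                 require_complete_age_sex = require_complete_age_sex),
            class = "eligibility_rules")
}

#' Build a brand- and dose-specific vaccination cohort
#'
#' Selects the persons vaccinated with \code{brand} at dose
#' \code{dose_number} who satisfy the eligibility rules, indexes them at
#' the day of that dose, and censors follow-up at
#' \code{min(index + risk_window_days, death, end of observation)}.
#' For dose-2 cohorts, the dose-1 brand must equal the dose-2 brand.
#' Persons with a dose gap at or below \code{rules$min_dose_gap_days} are
#' excluded from both dose cohorts.
#'
#' @param db a \code{vsd_database}.
#' @param brand brand label of the defining dose.
#' @param dose_number 1 or 2.
#' @param rules an [eligibility_rules()] object.
#' @param risk_window_days length of the at-risk window after index
#'   (default 28). Follow-up covers days \code{(index, index + 28]}; an
#'   event on the index day itself is not at risk.
#' @param arm label recorded on each entry, \code{"target"} or
#'   \code{"comparator"}.
#' @return a data.frame of cohort entries: \code{person_id}, \code{arm},
#'   \code{index_day}, \code{follow_up_end_day}, \code{censor_reason}
#'   (\code{window_end}, \code{death} or \code{observation_end}).
#' @export
build_cohort <- function(db, brand, dose_number, rules = eligibility_rules(),
                         risk_window_days = 28L,
                         arm = c("target", "comparator")) {
  arm <- match.arg(arm)
  if (!dose_number %in% c(1L, 2L))
    stopf("dose_number must be 1 or 2 (got %s)", dose_number,
          class = "vaxsafety_input_error")
  v <- db$vaccination
  known <- unique(v$brand[!is.na(v$brand) & v$brand != "unknown"])
  if (!brand %in% known)
    stopf("unknown brand label '%s' (brands present: %s)", brand,
          paste(known, collapse = ", "), class = "vaxsafety_input_error")

  d1 <- v[v$dose_number == 1L, ]
  d2 <- v[v$dose_number == 2L, ]
  sel <- v[v$dose_number == dose_number & v$brand == brand, ]
  if (!nrow(sel)) return(empty_cohort(arm))

  p <- db$person[match(sel$person_id, db$person$person_id), ]
  index_day <- sel$day
  d1_day <- d1$day[match(sel$person_id, d1$person_id)]
  d1_brand <- d1$brand[match(sel$person_id, d1$person_id)]
  d2_day <- d2$day[match(sel$person_id, d2$person_id)]
  d2_brand <- d2$brand[match(sel$person_id, d2$person_id)]

  # age at date of first dose
  age_at_d1 <- day_to_year(ifelse(is.na(d1_day), index_day, d1_day)) -
    p$birth_year

  keep <- rep(TRUE, nrow(sel))
  if (rules$require_complete_age_sex)
    keep <- keep & !is.na(p$birth_year) & !is.na(p$sex) & p$sex != ""
  if (rules$require_known_brand)
    keep <- keep & !is.na(sel$brand) & sel$brand != "unknown"
  keep <- keep & !is.na(age_at_d1) & age_at_d1 >= rules$min_age_years
  keep <- keep & (index_day - p$observation_start_day) >=
    rules$min_prior_history_days
  # dose-gap rule: persons whose recorded gap is <= threshold are removed
  # from both dose cohorts
  gap <- d2_day - d1_day
  keep <- keep & (is.na(gap) | gap > rules$min_dose_gap_days)
  if (dose_number == 2L)
    keep <- keep & !is.na(d1_brand) & d1_brand == brand &
      !is.na(d2_brand) & d2_brand == brand
  keep <- keep & index_day <= p$observation_end_day
  keep[is.na(keep)] <- FALSE

  sel <- sel[keep, ]; p <- p[keep, ]; index_day <- index_day[keep]
  if (!nrow(sel)) return(empty_cohort(arm))

  window_end <- index_day + as.integer(risk_window_days)
  death <- ifelse(is.na(p$death_day), Inf, p$death_day)
  fue <- pmin(window_end, death, p$observation_end_day)
  reason <- ifelse(fue == window_end, "window_end",
                   ifelse(fue == death, "death", "observation_end"))
  out <- data.frame(person_id = sel$person_id,
                    arm = arm,
                    index_day = as.integer(index_day),
                    follow_up_end_day = as.integer(fue),
                    censor_reason = reason,
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cohort <- function(arm) {
  data.frame(person_id = integer(0), arm = character(0),
             index_day = integer(0), follow_up_end_day = integer(0),
             censor_reason = character(0), stringsAsFactors = FALSE)
}

#' Randomly subsample a cohort
#'
#' Keeps exactly \code{round(fraction * n)} entries, drawn without
#' replacement; deterministic under \code{seed}.
#'
#' @param cohort a cohort data.frame from [build_cohort()].
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return the subsampled cohort, in person_id order.
#' @export
subsample_cohort <- function(cohort, fraction, seed = 1L) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1] (got %s)", fraction,
          class = "vaxsafety_input_error")
  if (fraction == 1) return(cohort)
  n_keep <- round(fraction * nrow(cohort))
  idx <- with_seed(seed, sample.int(nrow(cohort), n_keep))
  out <- cohort[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Baseline covariate extraction
#'
#' Builds the sparse person-by-covariate matrix used by the propensity
#' model: age (continuous), 10-year age-band indicators, a female-sex
#' indicator, index-year and index-month one-hot indicators, binary flags
#' for each condition concept observed strictly before the index day (all
#' available history), counts of drug/procedure/measurement utilisation
#' records in the half-open window \code{[index - 180, index)}, and
#' optionally composite comorbidity scores.
#'
#' @param db a \code{vsd_database}.
#' @param cohort a cohort data.frame (entries must reference persons in
#'   \code{db}).
#' @param condition_concepts character vector of condition concepts to
#'   flag; defaults to every event concept that is neither a utilisation
#'   concept nor an outcome/negative-control concept of the database's
#'   ground truth.
#' @param utilisation_concepts concepts counted in the 6-month window
#'   (default \code{drug}, \code{procedure}, \code{measurement}).
#' @param score_definitions optional list of [score_definition()] objects;
#'   each adds one integer-valued covariate column.
#' @param utilisation_window_days lookback for utilisation counts
#'   (default 180).
#' @return an object of class \code{covariate_matrix}: a list with
#'   \code{matrix} (a \code{dgCMatrix}, one row per cohort entry),
#'   \code{meta} (covariate_id, label, type) and \code{person_id}.
#' @export
extract_covariates <- function(db, cohort,
                               condition_concepts = NULL,
                               utilisation_concepts = c("drug", "procedure",
                                                        "measurement"),
                               score_definitions = NULL,
                               utilisation_window_days = 180L) {
  pm <- match(cohort$person_id, db$person$person_id)
  if (anyNA(pm))
    stopf("cohort person %s missing from database",
          cohort$person_id[which(is.na(pm))[1]],
          class = "vaxsafety_input_error")
  p <- db$person[pm, ]
  n <- nrow(cohort)
  index_day <- cohort$index_day

  if (is.null(condition_concepts)) {
    concepts <- unique(db$event$concept)
    drop <- c(utilisation_concepts, "thrombocytopenia_dx")
    if (!is.null(db$ground_truth))
      drop <- c(drop, db$ground_truth$outcomes$outcome)
    condition_concepts <- sort(setdiff(concepts, drop))
  }

  age <- day_to_year(index_day) - p$birth_year
  sexf <- as.numeric(p$sex == "female")
  yr <- day_to_year(index_day)
  mo <- day_to_month(index_day)
  band <- pmin(90L, (age %/% 10L) * 10L)

  cols <- list(); meta <- list()
  add_col <- function(id, label, type, values) {
    cols[[id]] <<- values
    meta[[id]] <<- data.frame(covariate_id = id, label = label, type = type,
                              stringsAsFactors = FALSE)
  }
  add_col("age", "age in years at index", "continuous", age)
  for (b in sort(unique(band)))
    add_col(sprintf("age_band_%d", b), sprintf("age %d-%d", b, b + 9),
            "binary", as.numeric(band == b))
  add_col("sex_female", "female sex", "binary", sexf)
  for (y in sort(unique(yr)))
    add_col(sprintf("index_year_%d", y), sprintf("index year %d", y),
            "one_hot", as.numeric(yr == y))
  for (m in sort(unique(mo)))
    add_col(sprintf("index_month_%02d", m), sprintf("index month %d", m),
            "one_hot", as.numeric(mo == m))

  ev <- db$event
  row_of <- integer(0)
  flag_values <- list()
  # condition flags: any event strictly before index
  for (cc in condition_concepts) {
    sub <- ev[ev$concept == cc, ]
    # aggregated first-day per person for the strict-before test
    if (nrow(sub)) {
      first_day <- tapply(sub$day, sub$person_id, min)
      fd <- first_day[as.character(cohort$person_id)]
      val <- as.numeric(!is.na(fd) & fd < index_day)
    } else val <- numeric(n)
    add_col(paste0("cond_", cc), sprintf("history of %s before index", cc),
            "binary", val)
    flag_values[[cc]] <- val
  }
  # utilisation counts in [index - window, index)
  for (uc in utilisation_concepts) {
    sub <- ev[ev$concept == uc, ]
    if (nrow(sub)) {
      idx <- match(sub$person_id, cohort$person_id)
      ok <- !is.na(idx) &
        sub$day >= index_day[idx] - utilisation_window_days &
        sub$day < index_day[idx]
      val <- numeric(n)
      if (any(ok)) {
        tab <- table(idx[ok])
        val[as.integer(names(tab))] <- as.numeric(tab)
      }
    } else val <- numeric(n)
    add_col(paste0("count_", uc),
            sprintf("%s records in prior %d days", uc,
                    utilisation_window_days),
            "continuous", val)
  }
  if (!is.null(score_definitions)) {
    flags_mat <- do.call(cbind, flag_values)
    if (is.null(flags_mat)) flags_mat <- matrix(0, n, 0)
    for (sd_ in score_definitions) {
      w <- sd_$components
      present <- intersect(names(w), colnames(flags_mat))
      sc <- if (length(present))
        as.numeric((flags_mat[, present, drop = FALSE] > 0) %*% w[present])
      else numeric(n)
      if (isTRUE(sd_$age_sex_points))
        sc <- sc + (age >= 65) + (age >= 75) + (p$sex == "female")
      add_col(paste0("score_", sd_$name), sprintf("%s score", sd_$name),
              "continuous", sc)
    }
  }

  mat <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  colnames(mat) <- names(cols)
  structure(list(matrix = methods::as(mat, "CsparseMatrix"),
                 meta = do.call(rbind, meta),
                 person_id = cohort$person_id),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("Covariate matrix: %d persons x %d covariates (%.1f%% non-zero)\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix))))
  invisible(x)
}

#' Combine covariate matrices row-wise, aligning covariate columns
#'
#' @param ... \code{covariate_matrix} objects.
#' @return a single \code{covariate_matrix} whose column set is the union.
#' @export
rbind_covariates <- function(...) {
  mats <- list(...)
  ids <- unique(unlist(lapply(mats, function(m) colnames(m$matrix))))
  aligned <- lapply(mats, function(m) {
    miss <- setdiff(ids, colnames(m$matrix))
    mm <- m$matrix
    if (length(miss)) {
      pad <- Matrix::Matrix(0, nrow(mm), length(miss), sparse = TRUE)
      colnames(pad) <- miss
      mm <- cbind(mm, pad)
    }
    mm[, ids, drop = FALSE]
  })
  meta <- unique(do.call(rbind, lapply(mats, `[[`, "meta")))
  meta <- meta[match(ids, meta$covariate_id), ]
  rownames(meta) <- NULL
  structure(list(matrix = do.call(rbind, aligned), meta = meta,
                 person_id = unlist(lapply(mats, `[[`, "person_id"))),
            class = "covariate_matrix")
}

#' Composite comorbidity score definition
#'
#' A weighted sum of binary condition components, optionally with the
#' CHA2DS2-VASc age and sex points (+1 for age 65-74, +2 for age >= 75,
#' +1 for female sex).
#'
#' @param name score name.
#' @param components named integer weights, one per condition concept;
#'   absent concepts contribute 0.
#' @param age_sex_points logical; add CHA2DS2-VASc age/sex points.
#' @return an object of class \code{score_definition}.
#' @export
score_definition <- function(name, components, age_sex_points = FALSE) {
  if (any(components < 0))
    stopf("score component weights must be >= 0",
          class = "vaxsafety_config_error")
  structure(list(name = name, components = components,
                 age_sex_points = age_sex_points),
            class = "score_definition")
}

#' Romano adaptation of the Charlson comorbidity index, restricted to the
#' condition concepts the synthetic generator emits.
#' @return a [score_definition()].
#' @export
charlson_romano_definition <- function() {
  score_definition("charlson_romano",
                   c(heart_failure = 1L, vascular_disease = 1L,
                     stroke = 1L, diabetes = 1L, cancer = 2L,
                     renal_disease = 2L))
}

#' CHA2DS2-VASc thrombosis risk score (congestive heart failure,
#' hypertension, diabetes, prior stroke, vascular disease, plus age and
#' sex points).
#' @return a [score_definition()].
#' @export
chads_vasc_definition <- function() {
  score_definition("chads_vasc",
                   c(heart_failure = 1L, hypertension = 1L, diabetes = 1L,
                     stroke = 2L, vascular_disease = 1L),
                   age_sex_points = TRUE)
}

#' Evaluate a comorbidity score for one person
#'
#' @param flags named numeric/logical vector of condition indicators;
#'   components absent from \code{flags} count as 0.
#' @param definition a [score_definition()].
#' @param age age in years at index.
#' @param sex \code{"female"} or \code{"male"}.
#' @return integer score.
#' @export
compute_score <- function(flags, definition, age, sex) {
  w <- definition$components
  present <- names(w)[names(w) %in% names(flags)]
  s <- sum(w[present] * as.numeric(flags[present] > 0))
  if (isTRUE(definition$age_sex_points)) {
    if (age >= 75) s <- s + 2L else if (age >= 65) s <- s + 1L
    if (identical(sex, "female")) s <- s + 1L
  }
  as.integer(s)
}
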