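#' Worked-example matched-cohort count table
#'
#' Matched-cohort cells (participants, person-years, events) per
#' (comparison, database, outcome, arm) for adenovirus- versus mRNA-based
#' covid-19 vaccination, as reported by a multinational network cohort
#' study. The table exists to demonstrate and test the incidence-rate and
#' rate-ratio arithmetic on real printed numbers; the patient-level data
#' behind it are not available.
#'
#' @return data.frame with columns \code{comparison}, \code{database},
#'   \code{outcome}, \code{arm}, \code{brand}, \code{dose},
#'   \code{participants}, \code{person_years}, \code{events}.
#' @export
matched_count_table <- function() {
  utils::read.csv(system.file("extdata", "matched_counts.csv",
                              package = "vaxsafety"),
                  stringsAsFactors = FALSE)
}

#' Recompute rates and rate ratios from a matched count table
#'
#' For every (comparison, database, outcome) pair of rows in a
#' [matched_count_table()]-shaped table, recomputes the per-arm incidence
#' rate per 1000 person-years with its exact CI and the crude Poisson
#' rate ratio from the cells.
#'
#' @param counts a data.frame shaped like [matched_count_table()].
#' @return data.frame with one row per (comparison, database, outcome):
#'   cells, \code{rate_target}, \code{rate_comparator} (with CI bounds)
#'   and \code{rr}, \code{rr_ci95_low}, \code{rr_ci95_high}.
#' @export
rates_from_counts <- function(counts = matched_count_table()) {
  key <- interaction(counts$comparison, counts$database, counts$outcome,
                     drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- counts[key == k, ]
    t <- d[d$arm == "target", ]; c_ <- d[d$arm == "comparator", ]
    rt <- incidence_rate(t$events, t$person_years)
    rc <- incidence_rate(c_$events, c_$person_years)
    irr <- poisson_irr(t$events, t$person_years, c_$events,
                       c_$person_years)
    data.frame(comparison = t$comparison, database = t$database,
               outcome = t$outcome,
               events_target = t$events, py_target = t$person_years,
               events_comparator = c_$events,
               py_comparator = c_$person_years,
               rate_target = rt$rate_per_1000py,
               rate_target_low = rt$ci95_low,
               rate_target_high = rt$ci95_high,
               rate_comparator = rc$rate_per_1000py,
               rate_comparator_low = rc$ci95_low,
               rate_comparator_high = rc$ci95_high,
               rr = irr$rr, rr_ci95_low = irr$ci95_low,
               rr_ci95_high = irr$ci95_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
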