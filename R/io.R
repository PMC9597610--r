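# Delimited-table persistence for synthetic databases: one comma-separated
# UTF-8 table per record type, each with a header row.

db_table_files <- c(person = "person.csv",
                    vaccination = "vaccination.csv",
                    event = "event.csv",
                    measurement = "measurement.csv")

required_columns <- list(
  person = c("person_id", "sex", "birth_year", "observation_start_day",
             "observation_end_day", "death_day"),
  vaccination = c("person_id", "brand", "dose_number", "day"),
  event = c("person_id", "concept", "day"),
  measurement = c("person_id", "day", "value"))

integer_columns <- list(
  person = c("person_id", "birth_year", "observation_start_day",
             "observation_end_day", "death_day"),
  vaccination = c("person_id", "dose_number", "day"),
  event = c("person_id", "day"),
  measurement = c("person_id", "day"))

#' Write a synthetic database to a directory of CSV tables
#'
#' Emits \code{person.csv}, \code{vaccination.csv}, \code{event.csv},
#' \code{measurement.csv}, and when ground truth is present
#' \code{ground_truth.csv} (per-outcome true rate ratios and injected log
#' bias) plus \code{ground_truth_person.csv} (true assignment
#' probabilities). \code{read_database(write_database(db, d))} returns a
#' database with identical tables.
#'
#' @param db a \code{vsd_database}.
#' @param directory path; created if missing.
#' @return the directory, invisibly.
#' @export
write_database <- function(db, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  for (tab in names(db_table_files)) {
    df <- db[[tab]][, required_columns[[tab]], drop = FALSE]
    utils::write.csv(df, file.path(directory, db_table_files[[tab]]),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(db$ground_truth)) {
    utils::write.csv(db$ground_truth$outcomes,
                     file.path(directory, "ground_truth.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(db$ground_truth$assignment,
                     file.path(directory, "ground_truth_person.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(directory)
}

read_table_checked <- function(path, table) {
  if (!file.exists(path))
    stopf("missing table file '%s'", path, class = "vaxsafety_parse_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required_columns[[table]], names(df))
  if (length(miss))
    stopf("table '%s': missing required column(s) %s", path,
          paste(miss, collapse = ", "), class = "vaxsafety_parse_error")
  for (col in integer_columns[[table]]) {
    v <- df[[col]]
    if (is.numeric(v)) {
      bad <- which(!is.na(v) & v != floor(v))
    } else {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & (is.na(num) | num != floor(num)))
      v <- num
    }
    if (length(bad))
      stopf("table '%s', line %d: column '%s' must be integer (got '%s')",
            path, bad[1] + 1L, col, df[[col]][bad[1]],
            class = "vaxsafety_parse_error")
    df[[col]] <- as.integer(v)
  }
  df
}

#' Read a synthetic database from a directory of CSV tables
#'
#' Inverse of [write_database()]. Structural invariants are checked on
#' load: at most one vaccination record per (person, dose), dose-2 after
#' dose-1, and clinical events inside their person's observation period.
#'
#' @param directory path containing the tables.
#' @return a \code{vsd_database}.
#' @export
read_database <- function(directory) {
  tabs <- lapply(names(db_table_files), function(tab)
    read_table_checked(file.path(directory, db_table_files[[tab]]), tab))
  names(tabs) <- names(db_table_files)
  gt <- NULL
  gt_path <- file.path(directory, "ground_truth.csv")
  if (file.exists(gt_path)) {
    outcomes <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
    assign_path <- file.path(directory, "ground_truth_person.csv")
    assignment <- if (file.exists(assign_path))
      utils::read.csv(assign_path, stringsAsFactors = FALSE) else NULL
    gt <- list(outcomes = outcomes, assignment = assignment)
  }
  db <- c(tabs, list(ground_truth = gt))
  class(db) <- "vsd_database"
  validate_database(db)
  db
}

#' Validate the structural invariants of a database
#'
#' @param db a \code{vsd_database}.
#' @return the database, invisibly; signals a classed error naming the
#'   violated constraint otherwise.
#' @export
validate_database <- function(db) {
  v <- db$vaccination
  if (nrow(v)) {
    key <- paste(v$person_id, v$dose_number)
    if (anyDuplicated(key))
      stopf("constraint violated: at most one vaccination record per (person, dose); duplicate %s",
            key[duplicated(key)][1], class = "vaxsafety_invariant_error")
    d1 <- v[v$dose_number == 1L, ]
    d2 <- v[v$dose_number == 2L, ]
    m <- match(d2$person_id, d1$person_id)
    bad <- which(!is.na(m) & d2$day <= d1$day[m])
    if (length(bad))
      stopf("constraint violated: dose-2 day must exceed dose-1 day (person %d)",
            d2$person_id[bad[1]], class = "vaxsafety_invariant_error")
  }
  e <- db$event
  if (nrow(e)) {
    m <- match(e$person_id, db$person$person_id)
    if (anyNA(m))
      stopf("constraint violated: event references unknown person %s",
            e$person_id[which(is.na(m))[1]],
            class = "vaxsafety_invariant_error")
    out <- e$day < db$person$observation_start_day[m] |
      e$day > db$person$observation_end_day[m]
    if (any(out))
      stopf("constraint violated: event outside observation period (person %d)",
            e$person_id[which(out)[1]], class = "vaxsafety_invariant_error")
  }
  mm <- db$measurement
  if (nrow(mm) && any(mm$value <= 0))
    stopf("constraint violated: platelet measurement values must be > 0",
          class = "vaxsafety_invariant_error")
  p <- db$person
  if (any(p$observation_start_day > p$observation_end_day))
    stopf("constraint violated: observation_start_day must not exceed observation_end_day",
          class = "vaxsafety_invariant_error")
  dd <- p$death_day
  if (any(!is.na(dd) & dd > p$observation_end_day))
    stopf("constraint violated: death_day must not exceed observation_end_day",
          class = "vaxsafety_invariant_error")
  invisible(db)
}
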