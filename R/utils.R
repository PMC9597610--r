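# Internal helpers shared across modules.

# The study calendar is an integer day index with day 0 = 1 January of the
# epoch year. Civil years are 365 days; months 1..11 have 30 days and month
# 12 absorbs the remainder. Only ordering and day arithmetic matter.
day_to_year <- function(day, epoch_year = 2021L) {
  as.integer(epoch_year + day %/% 365L)
}

day_to_month <- function(day) {
  as.integer(pmin(12L, (day %% 365L) %/% 30L + 1L))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed plus a character key (for example
#' `"db1/matching"`) to an integer below 2^31, so that adding a comparison
#' or database to a study does not perturb the seeds of existing stages.
#'
#' @param master integer master seed.
#' @param ... character components of the stage key.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(master)) + h) %% 2147480009)
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "vaxsafety_error")))
}

assert_finite <- function(x, what) {
  if (length(x) && (!is.numeric(x) || any(!is.finite(x))))
    stopf("'%s' must be finite numeric", what, class = "vaxsafety_config_error")
  invisible(x)
}
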