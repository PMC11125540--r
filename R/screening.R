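# Screening-side operations: schedule validation, surveillance lookup, and
# the cohort-level screening entry point.

SCHEDULE_MIN_AGE <- 20L
SCHEDULE_MAX_AGE <- 90L
SCHEDULE_MIN_GAP <- 5L
SCHEDULE_MAX_K <- 4L

#' Validate a colonoscopy screening schedule
#'
#' A valid schedule holds at most four integer ages between 20 and 90 with
#' pairwise gaps of at least five years.
#'
#' @param ages integer screening ages (years)
#' @return a `crc_schedule` object with element `ages` (sorted)
#' @export
validate_schedule <- function(ages) {
  if (inherits(ages, "crc_schedule")) return(ages)
  ages <- as.numeric(ages)
  if (length(ages) > SCHEDULE_MAX_K)
    stop_bad("at most ", SCHEDULE_MAX_K, " screening colonoscopies allowed (got ",
             length(ages), ")")
  if (length(ages)) {
    if (any(ages != round(ages)))
      stop_bad("screening ages must be integers")
    if (any(ages < SCHEDULE_MIN_AGE | ages > SCHEDULE_MAX_AGE))
      stop_bad("screening ages must lie in [", SCHEDULE_MIN_AGE, ", ",
               SCHEDULE_MAX_AGE, "]")
    ages <- sort(as.integer(ages))
    if (length(ages) > 1 && any(diff(ages) < SCHEDULE_MIN_GAP))
      stop_bad("screening ages must be at least ", SCHEDULE_MIN_GAP,
               " years apart")
  } else ages <- integer(0)
  structure(list(ages = ages), class = "crc_schedule")
}

#' @export
print.crc_schedule <- function(x, ...) {
  cat("<schedule>", if (length(x$ages)) paste(x$ages, collapse = ", ")
      else "(no screening)", "\n")
  invisible(x)
}

#' Next surveillance interval after a colonoscopy
#'
#' Pure table lookup of the surveillance guideline: `NULL` means the person
#' returns to the screening schedule.
#'
#' @param result a colonoscopy result (list with `findings_category` in
#'   `no_adenoma`, `1-2_early`, `>=3_or_advanced`, `cancer_detected`, and
#'   `age` in years)
#' @param guideline a [surveillance_guideline()]
#' @return interval in years, or `NULL`
#' @export
next_surveillance <- function(result, guideline) {
  cat_ <- result$findings_category
  if (!cat_ %in% c("no_adenoma", "1-2_early", ">=3_or_advanced",
                   "cancer_detected"))
    stop_bad("unknown findings category: ", cat_)
  if (!is.null(result$age) && result$age >= guideline$stop_age) return(NULL)
  switch(cat_,
         "no_adenoma" = NULL,
         "1-2_early" = guideline$interval_early,
         ">=3_or_advanced" = guideline$interval_advanced,
         "cancer_detected" = NULL)
}

findings_category <- function(n_early, n_adv, cancer_found) {
  if (cancer_found) "cancer_detected"
  else if (n_adv > 0 || n_early + n_adv >= 3) ">=3_or_advanced"
  else if (n_early > 0) "1-2_early"
  else "no_adenoma"
}

#' Run a cohort under a screening schedule
#'
#' Convenience wrapper around [run_cohort()]: validates the schedule, runs
#' the screened arm and returns the cohort outcome totals (and per-person
#' records on request). Screening, surveillance and diagnostic colonoscopies
#' are counted separately in the outcome vector.
#'
#' @inheritParams run_cohort
#' @export
apply_screening <- function(cohort, schedule, screen_seed = 1,
                            keep_persons = FALSE) {
  run_cohort(cohort, validate_schedule(schedule)$ages, screen_seed,
             keep_persons = keep_persons)
}
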