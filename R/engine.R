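# R-facing wrappers for the compiled microsimulation engine.
#
# A "cohort" is a handle to a precomputed set of potential natural
# histories: per person the other-cause death quarter, every potential
# adenoma with its staged trajectory and malignant transformation time, and
# every potential preclinical cancer with its staged course, symptomatic
# detection time and pre-drawn fate uniforms. Any screening schedule
# (including the empty one) is evaluated against this fixed history, which
# yields exact common random numbers across arms.

#' Initialize a simulated birth cohort
#'
#' Draws a cohort of persons at age 0 with sex and individual adenoma-risk
#' multipliers, together with their potential disease histories under the
#' given natural-history parameters. Identical `(n, seed, params)` give a
#' bit-identical cohort. The risk multiplier is log-normal with mean 1
#' (degenerate at 1 when `risk_sdlog = 0`).
#'
#' @param n cohort size (>= 1)
#' @param sex_fraction_male fraction of males
#' @param bundle a `crc_bundle` (or list with `nh` and `life_table`)
#' @param seed integer seed for the Mersenne-Twister stream
#' @return a `crc_cohort` handle
#' @export
init_cohort <- function(n, sex_fraction_male = 0.5, bundle, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop_bad("n must be a positive count")
  check_prob(sex_fraction_male, "sex_fraction_male")
  ptr <- cpp_simulate_history(
    nh_to_cpp(bundle$nh),
    life_table_death_cdf(bundle$life_table, 0),
    life_table_death_cdf(bundle$life_table, 1),
    as.integer(n), sex_fraction_male, as.numeric(seed))
  structure(list(ptr = ptr, n = as.integer(n), seed = seed,
                 sex_fraction_male = sex_fraction_male, bundle = bundle),
            class = "crc_cohort")
}

#' @export
print.crc_cohort <- function(x, ...) {
  s <- cpp_history_summary(x$ptr)
  cat("<crc_cohort> n =", s$n, " seed =", x$seed,
      "\n  potential adenomas:", s$n_adenomas,
      "\n  potential cancers: ", s$n_potential_cancers,
      "\n  mean risk multiplier:", round(s$mean_risk_multiplier, 4), "\n")
  invisible(x)
}

#' Person-level summary of a cohort's potential natural history
#' @param cohort a `crc_cohort`
#' @export
cohort_persons <- function(cohort) cpp_history_persons(cohort$ptr)

#' Lesion-level tables of a cohort's potential natural history
#' @param cohort a `crc_cohort`
#' @export
cohort_lesions <- function(cohort) cpp_history_lesions(cohort$ptr)

# outcome columns produced by the engine
OUTCOME_COLS <- c("cases", "crc_deaths", "compl_deaths", "colos_screen",
                  "colos_surv", "colos_diag", "invitations", "polypectomies",
                  "complications", "adenomas_removed", "life_years",
                  "disc_life_years", "lyl", "disc_lyl", "cost", "disc_cost")

schedule_matrix <- function(schedules) {
  if (is.null(schedules)) schedules <- list(integer(0))
  if (is.numeric(schedules) && is.null(dim(schedules)))
    schedules <- list(schedules)
  if (is.list(schedules)) {
    k <- max(1L, max(vapply(schedules, length, 1L)))
    m <- matrix(NA_real_, length(schedules), k)
    for (i in seq_along(schedules)) {
      s <- schedules[[i]]
      if (length(s)) m[i, seq_along(s)] <- as.numeric(sort(s))
    }
    m
  } else as.matrix(schedules)
}

#' Simulate a cohort to death under a screening schedule
#'
#' Runs every person in the cohort from birth to death under the given
#' schedule (or none). With `schedule = NULL` no screening occurs but
#' symptomatic diagnosis (with its diagnostic colonoscopy) still does.
#' Because the cohort's natural history is fixed, repeated calls with
#' different schedules are paired person-for-person (common random numbers).
#'
#' @param cohort a `crc_cohort`
#' @param schedule integer screening ages (validated), or `NULL`
#' @param screen_seed seed for the screening draws (detection, reach,
#'   adherence, complications); keep fixed across arms for CRN
#' @param keep_persons return the per-person event table as well
#' @return a list with `outcomes` (named numeric vector of cohort totals)
#'   and, if requested, `persons` (one row per person)
#' @export
run_cohort <- function(cohort, schedule = NULL, screen_seed = 1,
                       keep_persons = FALSE) {
  b <- cohort$bundle
  if (!is.null(schedule) && length(schedule))
    schedule <- validate_schedule(schedule)$ages
  m <- eval_schedules(cohort, list(schedule %||% integer(0)), screen_seed)
  res <- list(outcomes = m[1, ])
  if (keep_persons) {
    res$persons <- cpp_eval_persons(
      cohort$ptr, nh_to_cpp(b$nh), colo_to_cpp(b$colo),
      unclass(b$guideline), cost_to_cpp(b$costs),
      if (length(schedule)) as.numeric(schedule) else numeric(0),
      as.numeric(screen_seed),
      b$costs$discount_rate_annual, b$costs$discount_anchor_age)
  }
  res
}

#' Evaluate many schedules against one cohort
#'
#' @param cohort a `crc_cohort`
#' @param schedules list of integer age vectors (use `integer(0)` for the
#'   no-screening arm) or a numeric matrix with NA padding
#' @param screen_seed seed for screening draws, shared across schedules
#' @return numeric matrix, one row per schedule, columns [OUTCOME_COLS]
#' @export
eval_schedules <- function(cohort, schedules, screen_seed = 1) {
  b <- cohort$bundle
  m <- schedule_matrix(schedules)
  cpp_eval_schedules(cohort$ptr, nh_to_cpp(b$nh), colo_to_cpp(b$colo),
                     unclass(b$guideline), cost_to_cpp(b$costs), m,
                     as.numeric(screen_seed),
                     b$costs$discount_rate_annual,
                     b$costs$discount_anchor_age)
}

#' Export a per-person event table (RawCohortRecord) as CSV
#' @param cohort a `crc_cohort`
#' @param schedule screening ages or NULL
#' @param path output CSV path
#' @param screen_seed screening seed
#' @export
export_cohort_record <- function(cohort, schedule, path, screen_seed = 1) {
  rec <- run_cohort(cohort, schedule, screen_seed, keep_persons = TRUE)
  utils::write.csv(rec$persons, path, row.names = FALSE)
  invisible(path)
}

# ----------------------------------------------------------- benchmarks ---

#' Cross-sectional benchmarks from a no-screening simulation
#'
#' Simulates `n` persons without screening and tabulates, per sex and 5-year
#' age band, the early- and advanced-adenoma prevalence at the band midpoint
#' (among persons alive and undiagnosed) and the CRC incidence per 100,000
#' person-years at risk.
#'
#' @param bundle a `crc_bundle` (its `nh` is the parameter set benchmarked)
#' @param n persons to simulate (>= 1e4 recommended; smaller n sets the
#'   `small_n` flag)
#' @param seed simulation seed
#' @param band_starts lower edges of the age bands (years)
#' @return a `crc_benchmarks` data frame
#' @export
make_benchmarks_from_params <- function(bundle, n = 1e5, seed = 1,
                                        band_starts = seq(20, 95, by = 5)) {
  co <- init_cohort(n, 0.5, bundle, seed)
  bm <- cpp_benchmarks(co$ptr, nh_to_cpp(bundle$nh),
                       as.numeric(band_starts), 5)
  attr(bm, "small_n") <- n < 1e4
  if (n < 1e4)
    warning("n < 1e4: benchmark table flagged as small_n", call. = FALSE)
  class(bm) <- c("crc_benchmarks", "data.frame")
  bm
}

#' Fit a scalar adenoma-initiation multiplier to benchmark prevalences
#'
#' One-dimensional calibration: finds the multiplier `m` on the adenoma
#' initiation rates whose simulated early+advanced adenoma prevalence curve
#' minimizes the summed squared relative error against the benchmark table.
#' Bracketed scalar search on log(m); everything else in `bundle` is fixed.
#'
#' @param benchmarks target `crc_benchmarks` table
#' @param bundle initial parameter bundle
#' @param n persons per evaluation
#' @param seed simulation seed (fixed across evaluations: common random
#'   numbers smooth the objective)
#' @param interval multiplier search interval
#' @return the bundle with scaled initiation rates; attributes `multiplier`
#'   and `converged`
#' @export
calibrate_adenoma_scale <- function(benchmarks, bundle, n = 2e4, seed = 1,
                                    interval = c(0.05, 8)) {
  tgt <- benchmarks[order(benchmarks$sex, benchmarks$age_band_start), ]
  tv <- tgt$early_adenoma_prev + tgt$advanced_adenoma_prev
  if (all(tv == 0)) {
    out <- scale_adenoma_init(bundle, 0)
    attr(out, "multiplier") <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  bands <- sort(unique(tgt$age_band_start))
  # precision weighting: squared relative errors are weighted by the
  # cross-sectional denominators so that sparse old-age bands do not
  # dominate the objective with Monte-Carlo noise
  w <- tgt$n_alive_mid
  keep <- tv > 0 & w >= 50
  obj <- function(logm) {
    m <- exp(logm)
    bm <- suppressWarnings(
      make_benchmarks_from_params(scale_adenoma_init(bundle, m), n, seed,
                                  band_starts = bands))
    bm <- bm[order(bm$sex, bm$age_band_start), ]
    sv <- bm$early_adenoma_prev + bm$advanced_adenoma_prev
    sum(w[keep] * ((sv[keep] - tv[keep]) / tv[keep])^2) / sum(w[keep])
  }
  # the objective is noisy: locate the basin on a coarse log-spaced grid,
  # then refine with a bracketed scalar search between the neighbors
  grid <- seq(log(interval[1]), log(interval[2]), length.out = 13)
  vals <- vapply(grid, obj, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  op <- stats::optimize(obj, interval = c(lo, hi), tol = 0.005)
  m <- exp(op$minimum)
  if (op$objective > vals[i0]) m <- exp(grid[i0])
  out <- scale_adenoma_init(bundle, m)
  attr(out, "multiplier") <- m
  attr(out, "converged") <- min(op$objective, vals[i0]) < 1
  out
}

# multiply the adenoma initiation rates (probability scale, capped at 1)
scale_adenoma_init <- function(bundle, m) {
  b <- bundle
  b$nh$init_rate_m <- pmin(1, b$nh$init_rate_m * m)
  b$nh$init_rate_f <- pmin(1, b$nh$init_rate_f * m)
  b
}
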