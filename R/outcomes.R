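# Outcome and economics layer: turns engine outcome vectors into the four
# objective reductions, per-1000 summaries and ICERs.

#' Discount a value to the reference age
#'
#' `amount / (1 + rate)^(age_years - anchor_age)`; the factor is clamped at
#' 1 before the anchor age, so flows before age 20 are neither discounted
#' nor inflated.
#'
#' @param amount value (cost or life years)
#' @param age_years age at which the flow occurs
#' @param rate annual discount rate (default 3%)
#' @param anchor_age discounting reference age (default 20)
#' @export
discount <- function(amount, age_years, rate = 0.03, anchor_age = 20) {
  if (rate < 0) stop_bad("discount rate must be >= 0")
  f <- (1 + rate)^-(pmax(age_years - anchor_age, 0))
  amount * f
}

#' Assign treatment-cost categories and accrue costs for one person
#'
#' Independent R implementation of the quarterly cost-accrual rule, used as
#' an oracle against the compiled engine: each quarter from diagnosis gets
#' exactly one treatment category with precedence terminal (last 12 months
#' before CRC death) > initial (first 12 months after diagnosis) >
#' follow-up, and nothing accrues beyond 5 years (20 quarters) after
#' diagnosis. Procedure events are costed at their quarter; a diagnosed
#' patient dying of a non-CRC cause incurs the unrelated-death terminal
#' cost.
#'
#' @param record list with `dx_q`, `dx_stage` (1-4), `death_q`, `cause`
#'   (`"crc"`, `"other"` or `"complication"`), and optionally `procedures`
#'   (data frame with `quarter`, `cost`)
#' @param costs a [cost_params()]
#' @return list with `by_quarter` (quarter, category, cost, disc_cost) and
#'   totals `cost`, `disc_cost`
#' @export
accrue_costs <- function(record, costs) {
  rows <- NULL
  add <- function(quarter, category, amount) {
    rbind(rows, data.frame(
      quarter = quarter, category = category, cost = amount,
      disc_cost = discount(amount, quarter / 4 + 0.125,
                           costs$discount_rate_annual,
                           costs$discount_anchor_age)))
  }
  if (!is.null(record$procedures) && nrow(record$procedures)) {
    for (i in seq_len(nrow(record$procedures)))
      rows <- add(record$procedures$quarter[i], "procedure",
                  record$procedures$cost[i])
  }
  if (!is.null(record$dx_q) && !is.na(record$dx_q)) {
    dx <- record$dx_q
    last <- min(record$death_q, dx + costs$horizon_quarters - 1)
    cats <- character(0)
    for (j in dx:last) {
      cat_ <- if (identical(record$cause, "crc") && j >= record$death_q - 3)
        "terminal12mo"
      else if (j <= dx + 3) "initial12mo"
      else "followup"
      cats <- c(cats, cat_)
      rows <- add(j, cat_, costs$treatment_cost[record$dx_stage, cat_])
    }
    if (!identical(record$cause, "crc"))
      rows <- add(record$death_q, "death_unrelated",
                  costs$death_unrelated_terminal_cost)
  }
  if (is.null(rows))
    rows <- data.frame(quarter = integer(0), category = character(0),
                       cost = numeric(0), disc_cost = numeric(0))
  list(by_quarter = rows, cost = sum(rows$cost),
       disc_cost = sum(rows$disc_cost))
}

#' The four objective reductions of a screened arm versus no screening
#'
#' Each component is `100 * (baseline - screened) / baseline`: CRC mortality
#' (CRC deaths), CRC incidence (diagnosed cases), discounted life years lost
#' (to CRC death and screening-procedure deaths, person-paired against the
#' no-screening arm), and total costs. A zero baseline component yields `NA`
#' with the `flagged` attribute set.
#'
#' @param screened,baseline outcome vectors from [eval_schedules()] /
#'   [run_cohort()]
#' @return named numeric vector of class `crc_objectives` with components
#'   `mortality_reduction_pct`, `incidence_reduction_pct`,
#'   `discounted_lyl_reduction_pct`, `cost_reduction_pct`
#' @export
compute_objectives <- function(screened, baseline) {
  pick <- c(mortality_reduction_pct = "crc_deaths",
            incidence_reduction_pct = "cases",
            discounted_lyl_reduction_pct = "disc_lyl",
            cost_reduction_pct = "cost")
  out <- vapply(pick, function(f) {
    b <- as.numeric(baseline[f]); s <- as.numeric(screened[f])
    if (b == 0) NA_real_ else 100 * (b - s) / b
  }, numeric(1))
  names(out) <- names(pick)
  attr(out, "flagged") <- names(out)[is.na(out)]
  class(out) <- c("crc_objectives", class(out))
  out
}

OBJECTIVES <- c("discounted_lyl_reduction_pct", "incidence_reduction_pct",
                "mortality_reduction_pct", "cost_reduction_pct")

# short aliases accepted on interfaces
OBJECTIVE_ALIASES <- c(dlyl = "discounted_lyl_reduction_pct",
                       incidence = "incidence_reduction_pct",
                       mortality = "mortality_reduction_pct",
                       cost = "cost_reduction_pct")

resolve_objective <- function(objective) {
  if (objective %in% names(OBJECTIVE_ALIASES))
    objective <- OBJECTIVE_ALIASES[[objective]]
  if (!objective %in% OBJECTIVES)
    stop_bad("unknown objective; use one of ",
             paste(names(OBJECTIVE_ALIASES), collapse = ", "))
  objective
}

#' Per-1000 summary metrics of a screened arm versus no screening
#'
#' @inheritParams compute_objectives
#' @param n cohort size
#' @return named vector: life years gained per 1000 (absolute,
#'   undiscounted), discounted LYG per 1000, colonoscopies per 1000 (all
#'   purposes), colonoscopies per life year gained, colonoscopies per case
#'   prevented; undefined ratios are `NA`
#' @export
summary_metrics <- function(screened, baseline, n) {
  lyg <- as.numeric(baseline["lyl"] - screened["lyl"])
  dlyg <- as.numeric(baseline["disc_lyl"] - screened["disc_lyl"])
  colos <- as.numeric(screened["colos_screen"] + screened["colos_surv"] +
                        screened["colos_diag"])
  prevented <- as.numeric(baseline["cases"] - screened["cases"])
  c(lyg_per_1000 = lyg / n * 1000,
    dlyg_per_1000 = dlyg / n * 1000,
    colonoscopies_per_1000 = colos / n * 1000,
    colonoscopies_per_lyg = if (lyg > 0) colos / lyg else NA_real_,
    colonoscopies_per_case_prevented =
      if (prevented > 0) colos / prevented else NA_real_)
}

#' Incremental cost-effectiveness ratio of strategy a versus comparator b
#'
#' `(disc_cost_a - disc_cost_b) / (dLY_a - dLY_b)` in discounted currency
#' per discounted life year gained; negative values are cost saving. If `a`
#' does not save more discounted life years than `b` the pair is flagged
#' (`dominated` or `undefined`).
#'
#' @param a,b outcome vectors (need `disc_cost` and `disc_life_years`)
#' @return list with `icer`, `d_cost`, `d_ly`, `flag`
#' @export
icer <- function(a, b) {
  d_cost <- as.numeric(a["disc_cost"] - b["disc_cost"])
  d_ly <- as.numeric(a["disc_life_years"] - b["disc_life_years"])
  if (d_ly == 0)
    return(list(icer = NA_real_, d_cost = d_cost, d_ly = 0,
                flag = "undefined"))
  flag <- if (d_ly < 0) "dominated_ordering" else "ok"
  list(icer = d_cost / d_ly, d_cost = d_cost, d_ly = d_ly, flag = flag)
}
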