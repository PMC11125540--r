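# One-way sensitivity scans, bound scenarios, rank-sum testing, and
# risk-stratified (personalized) schedule optimization.

SCAN_PARAMS <- c("adenoma_risk", "detection", "adherence", "survival",
                 "complications")

#' Scale one key parameter of a bundle
#'
#' Applies a multiplier to one of the five sensitivity parameters;
#' probabilities are capped at 1 ("bounded at 100%"), in which case the
#' returned bundle carries a `capped` attribute.
#'
#' @param bundle a `crc_bundle`
#' @param param one of `"adenoma_risk"` (adenoma initiation rates),
#'   `"detection"` (adenoma and cancer detection sensitivities),
#'   `"adherence"`, `"survival"` (5-year stage survival), `"complications"`
#'   (complication probabilities)
#' @param multiplier positive factor
#' @export
scale_bundle <- function(bundle, param, multiplier) {
  if (!param %in% SCAN_PARAMS)
    stop_bad("param must be one of ", paste(SCAN_PARAMS, collapse = ", "))
  if (multiplier < 0) stop_bad("multiplier must be >= 0")
  b <- bundle
  capped <- FALSE
  capmul <- function(x) {
    y <- x * multiplier
    if (any(y > 1)) capped <<- TRUE
    pmin(1, y)
  }
  switch(param,
    adenoma_risk = { b <- scale_adenoma_init(b, multiplier) },
    detection = {
      b$colo$sens_adenoma <- capmul(b$colo$sens_adenoma)
      b$colo$sens_cancer <- capmul(b$colo$sens_cancer)
    },
    adherence = { b$colo$adherence <- capmul(b$colo$adherence) },
    survival = { b$nh$surv5 <- capmul(b$nh$surv5) },
    complications = { b$colo$compl_prob <- capmul(b$colo$compl_prob) })
  attr(b, "capped") <- capped
  b
}

#' One-way sensitivity scan of the optimal schedule
#'
#' For each multiplier, re-derives the per-objective optimal schedule with
#' the same search procedure and seed policy as the baseline (brute force
#' for k <= 2, metaheuristic otherwise) and reports the optimal ages.
#'
#' @param bundle baseline `crc_bundle`
#' @param param scanned parameter (see [scale_bundle()])
#' @param multipliers scan multipliers (1 is always included)
#' @param k number of colonoscopies
#' @param objectives objective(s) to optimize
#' @param n,replicates,seed evaluator configuration
#' @param coarse_by,iterations,population search configuration
#' @return data frame: one row per multiplier x objective with optimal ages
#'   and the objective value; attribute `per_replicate` keeps the replicate
#'   spread of each optimum
#' @export
one_way_scan <- function(bundle, param,
                         multipliers = c(0.5, 0.75, 0.9, 1.1, 1.25, 1.5),
                         k = 1, objectives = "dlyl", n = 2e4, replicates = 3,
                         seed = 1, coarse_by = NULL, iterations = 12,
                         population = 16) {
  multipliers <- sort(unique(c(1, multipliers)))
  objectives <- vapply(objectives, resolve_objective, character(1))
  rows <- list()
  spread <- list()
  for (m in multipliers) {
    b <- scale_bundle(bundle, param, m)
    if (isTRUE(attr(b, "capped")))
      message("note: ", param, " x", m, " capped at 100%")
    ev <- make_evaluator(b, n = n, replicates = replicates, seed = seed)
    for (obj in objectives) {
      best <- if (k <= 2) {
        brute_force_optimize(ev, k, objectives = obj,
                             coarse_by = coarse_by)$best[[obj]]
      } else {
        metaheuristic_search(ev, k, iterations = iterations,
                             population = population, seed = seed)$best[[obj]]
      }
      agecols <- grep("^age", names(best), value = TRUE)
      row <- data.frame(param = param, multiplier = m, objective = obj,
                        best[, c(agecols, obj)], row.names = NULL)
      rows[[length(rows) + 1]] <- row
      spread[[length(spread) + 1]] <- attr(best, "per_replicate")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_replicate") <- spread
  out
}

#' Evaluate the named bound scenarios at a fixed schedule
#'
#' Scenarios: CRC survival hazard ratios (survival mapped on the hazard
#' scale, `S -> S^HR`), total serious-complication probabilities (type mix
#' preserved), and cecal intubation rates (each of the three boundary
#' passage probabilities set to the cube root of the target rate).
#'
#' @param bundle baseline `crc_bundle`
#' @param schedule screening ages evaluated in every scenario
#' @param hr survival hazard ratios
#' @param complication_totals total serious-complication probabilities
#' @param intubation_rates cecal intubation rates
#' @param n,replicates,seed evaluator configuration
#' @return data frame of scenario outcomes (medians across replicates)
#' @export
bound_scenarios <- function(bundle, schedule = c(50, 60, 70),
                            hr = c(0.39, 1, 2),
                            complication_totals = c(0.001, 0.015),
                            intubation_rates = 0.70,
                            n = 2e4, replicates = 3, seed = 1) {
  if (any(hr <= 0)) stop_bad("hazard ratios must be positive")
  scenarios <- list(list(label = "baseline", bundle = bundle))
  for (h in hr) {
    if (h == 1) next
    b <- bundle
    b$nh$surv5 <- bundle$nh$surv5^h
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("survival_hr_%g", h), bundle = b)
  }
  for (ct in complication_totals) {
    b <- bundle
    tot <- sum(bundle$colo$compl_prob)
    b$colo$compl_prob <- if (tot > 0) bundle$colo$compl_prob * ct / tot
      else rep(ct / 3, 3)
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("complications_%g", ct), bundle = b)
  }
  for (ir in intubation_rates) {
    b <- bundle
    b$colo$reach <- rep(ir^(1 / 3), 3)
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("intubation_%g", ir), bundle = b)
  }
  rows <- lapply(scenarios, function(sc) {
    ev <- make_evaluator(sc$bundle, n = n, replicates = replicates,
                         seed = seed)
    l <- evaluate_schedules_cached(ev, list(schedule))
    cbind(data.frame(scenario = sc$label), l[, setdiff(names(l), "key")])
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact null enumeration (dynamic programming over rank sums) for combined
#' sample sizes up to 20 without ties; otherwise the normal approximation
#' with tie correction.
#'
#' @param a,b numeric samples
#' @return list with `statistic` (rank sum of `a`), `p_value`, `method`
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop_bad("samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  ties <- any(duplicated(c(a, b)))
  if (N <= 20 && !ties) {
    # f[k, s]: number of k-subsets of ranks 1..N with sum s
    maxs <- N * (N + 1) / 2
    f <- matrix(0, n1 + 1, maxs + 1)
    f[1, 1] <- 1
    for (v in seq_len(N)) {
      for (k in min(n1, v):1) {
        s <- seq(0, maxs - v)
        f[k + 1, s + v + 1] <- f[k + 1, s + v + 1] + f[k, s + 1]
      }
    }
    dist <- f[n1 + 1, ]
    tot <- sum(dist)
    lo <- sum(dist[seq_len(w + 1)])            # P(W <= w)
    hi <- sum(dist[(w + 1):(maxs + 1)])        # P(W >= w)
    p <- min(1, 2 * min(lo, hi) / tot)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- n1 * (N + 1) / 2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = w, p_value = 1,
                               method = "normal_ties"))
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = w, p_value = p, method = "normal_ties")
  }
}

#' Risk multipliers of a two-group stratification
#'
#' Solves `f * m_high + (1 - f) * m_low = 1` and `m_high = rr * m_low`, so
#' the population-average initiation rate is preserved exactly.
#'
#' @param risk_ratio high:low risk ratio
#' @param high_fraction fraction in the high-risk group
#' @export
stratification_multipliers <- function(risk_ratio, high_fraction = 0.25) {
  if (risk_ratio <= 0 || high_fraction <= 0 || high_fraction >= 1)
    stop_bad("infeasible stratification")
  m_low <- 1 / ((1 - high_fraction) + high_fraction * risk_ratio)
  c(m_low = m_low, m_high = risk_ratio * m_low)
}

#' Optimize schedules separately for risk- (and sex-) stratified groups
#'
#' Builds low- and high-risk bundles by scaling adenoma initiation with the
#' multipliers from [stratification_multipliers()], re-derives the optimal
#' schedule in each group, and optionally per sex.
#'
#' @param bundle baseline `crc_bundle`
#' @param risk_ratio high:low risk ratio of the hypothetical test
#' @param high_fraction fraction labeled high risk
#' @param k,objective,n,replicates,seed,coarse_by,iterations,population
#'   search configuration (brute force for k <= 2, metaheuristic otherwise)
#' @param by_sex also optimize male-only and female-only cohorts
#' @return data frame, one row per group with optimal ages
#' @export
stratify_and_optimize <- function(bundle, risk_ratio, high_fraction = 0.25,
                                  k = 1, objective = "dlyl", n = 2e4,
                                  replicates = 3, seed = 1, coarse_by = NULL,
                                  iterations = 12, population = 16,
                                  by_sex = FALSE) {
  objective <- resolve_objective(objective)
  mult <- stratification_multipliers(risk_ratio, high_fraction)
  groups <- list(low_risk = list(bundle = scale_adenoma_init(bundle, mult["m_low"]),
                                 frac_male = 0.5),
                 high_risk = list(bundle = scale_adenoma_init(bundle, mult["m_high"]),
                                  frac_male = 0.5))
  if (by_sex) {
    groups$male <- list(bundle = bundle, frac_male = 1)
    groups$female <- list(bundle = bundle, frac_male = 0)
  }
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    ev <- make_evaluator(g$bundle, n = n, replicates = replicates,
                         seed = seed, sex_fraction_male = g$frac_male)
    best <- if (k <= 2)
      brute_force_optimize(ev, k, objectives = objective,
                           coarse_by = coarse_by)$best[[objective]]
    else
      metaheuristic_search(ev, k, iterations = iterations,
                           population = population, seed = seed)$best[[objective]]
    agecols <- grep("^age", names(best), value = TRUE)
    data.frame(group = gn, risk_ratio = risk_ratio,
               multiplier = switch(gn, low_risk = mult[["m_low"]],
                                   high_risk = mult[["m_high"]], 1),
               best[, c(agecols, objective)], row.names = NULL)
  })
  do.call(rbind, rows)
}
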