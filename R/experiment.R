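# Config-driven experiment runner: replicate/seed management, summary
# statistics, ICER ladders and file outputs with a reproducibility manifest.

#' Summary statistics over replicates
#'
#' @param values numeric replicate values
#' @return named vector: median, mean, sd, q25, q75, iqr, p10, p90, and the
#'   number of outliers (outside 1.5 IQR of the quartiles)
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  qs <- stats::quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE,
                        type = 7)
  iqr <- qs[3] - qs[2]
  out <- sum(values < qs[2] - 1.5 * iqr | values > qs[3] + 1.5 * iqr)
  c(median = stats::median(values), mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    q25 = qs[2], q75 = qs[3], iqr = iqr, p10 = qs[1], p90 = qs[4],
    n_outliers = out)
}

#' ICER ladder over an ordered set of strategies
#'
#' Sorts strategies by discounted life years gained, flags dominated
#' strategies (more costly and less effective than a predecessor) and
#' extended-dominated ones (a higher ICER than the next step up), computes
#' successive ICERs along the efficient frontier and compares them to the
#' cost-effectiveness threshold.
#'
#' @param strategies data frame with columns `label`, `disc_cost`,
#'   `disc_ly` (both incremental to, or absolute under, a common baseline)
#' @param threshold willingness-to-pay per discounted life year
#' @return the data frame ordered by effectiveness with `icer`, `dominated`,
#'   `extended_dominated`, `cost_effective` columns
#' @export
icer_ladder <- function(strategies, threshold = 1e5) {
  s <- strategies[order(strategies$disc_ly), , drop = FALSE]
  n <- nrow(s)
  s$dominated <- FALSE
  s$extended_dominated <- FALSE
  s$icer <- NA_real_
  # strong dominance: a (weakly) more effective strategy that is cheaper;
  # the least effective row is the comparison anchor and is never flagged
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(n)) {
      if (j != i && s$disc_ly[j] >= s$disc_ly[i] &&
          s$disc_cost[j] < s$disc_cost[i]) {
        s$dominated[i] <- TRUE
        break
      }
    }
  }
  repeat {
    idx <- which(!s$dominated & !s$extended_dominated)
    if (length(idx) > 1) {
      for (m in 2:length(idx)) {
        i <- idx[m]; pr <- idx[m - 1]
        d_ly <- s$disc_ly[i] - s$disc_ly[pr]
        s$icer[i] <- if (d_ly > 0)
          (s$disc_cost[i] - s$disc_cost[pr]) / d_ly else Inf
      }
      ic <- s$icer[idx[-1]]
      bad <- which(diff(ic) < 0)
      if (length(bad)) {
        s$extended_dominated[idx[bad[1] + 1]] <- TRUE
        s$icer[] <- NA_real_
        next
      }
    }
    break
  }
  s$cost_effective <- !s$dominated & !s$extended_dominated &
    (is.na(s$icer) | s$icer <= threshold)
  s
}

#' Run a configured experiment and write its outputs
#'
#' Spawns `replicates` simulations with per-replicate seeds derived
#' deterministically from the base seed, writes tidy CSV/JSON outputs and a
#' run manifest. Experiment kinds: `natural_history` (no-screening
#' benchmarks), `single_schedule`, `optimize_k`, `sensitivity`,
#' `personalization`, `icer_ladder`.
#'
#' @param config list (or path to a JSON file) with fields `kind`,
#'   `population`, `replicates`, `seed`, `out_dir`, and kind-specific
#'   fields (`schedule`, `k`, `objective`, `param`, `risk_ratio`, ...);
#'   `scenario` selects the parameter bundle (default `"default_us"`),
#'   or `bundle_path` points to a JSON bundle
#' @return list of result objects (invisibly); files under `out_dir`
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  kind <- config$kind %||% stop_bad("config needs a 'kind'")
  n <- config$population %||% 2e4
  if (n < 1e3) stop_bad("population must be >= 1000")
  reps <- config$replicates %||% 10
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% stop_bad("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- if (!is.null(config$bundle_path)) read_bundle(config$bundle_path)
    else make_default_params(config$scenario %||% "default_us")
  res <- switch(kind,
    natural_history = {
      bm <- make_benchmarks_from_params(bundle, n = n, seed = seed)
      write_table_csv(bm, file.path(out_dir, "benchmarks.csv"))
      list(benchmarks = bm)
    },
    single_schedule = {
      ev <- make_evaluator(bundle, n = n, replicates = reps, seed = seed)
      l <- evaluate_schedules_cached(ev, list(config$schedule))
      pr <- attr(l, "per_replicate")[[1]]
      utils::write.csv(cbind(replicate = seq_len(nrow(pr)),
                             as.data.frame(pr)),
                       file.path(out_dir, "outcomes.csv"), row.names = FALSE)
      summ <- apply(pr, 2, replicate_summary)
      jsonlite::write_json(as.data.frame(summ),
                           file.path(out_dir, "summary.json"),
                           digits = NA, pretty = TRUE)
      list(landscape = l, replicates = pr, summary = summ)
    },
    optimize_k = {
      ev <- make_evaluator(bundle, n = n, replicates = reps, seed = seed)
      k <- config$k %||% 1
      r <- if (k <= 2) brute_force_optimize(ev, k,
                                            coarse_by = config$coarse_by)
        else metaheuristic_search(ev, k,
                                  iterations = config$iterations %||% 15,
                                  population = config$population_size %||% 20,
                                  seed = seed)
      land <- if (k <= 2) r$landscape else r$archive
      utils::write.csv(land[, setdiff(names(land), "key")],
                       file.path(out_dir, sprintf("landscape_k%d.csv", k)),
                       row.names = FALSE)
      front <- land[kung_front(as.matrix(land[, OBJECTIVES])), ]
      jsonlite::write_json(front[, setdiff(names(front), "key")],
                           file.path(out_dir, sprintf("pareto_k%d.json", k)),
                           digits = NA, pretty = TRUE, dataframe = "rows")
      r
    },
    sensitivity = {
      sc <- one_way_scan(bundle, config$param %||% "adenoma_risk",
                         k = config$k %||% 1,
                         objectives = config$objective %||% "dlyl",
                         n = n, replicates = reps, seed = seed,
                         coarse_by = config$coarse_by)
      utils::write.csv(sc, file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
      list(scan = sc)
    },
    personalization = {
      st <- stratify_and_optimize(bundle, config$risk_ratio %||% 2,
                                  k = config$k %||% 1,
                                  objective = config$objective %||% "dlyl",
                                  n = n, replicates = reps, seed = seed,
                                  coarse_by = config$coarse_by)
      utils::write.csv(st, file.path(out_dir, "personalization.csv"),
                       row.names = FALSE)
      list(stratified = st)
    },
    icer_ladder = {
      ev <- make_evaluator(bundle, n = n, replicates = reps, seed = seed)
      scheds <- config$schedules %||% stop_bad("icer_ladder needs 'schedules'")
      if (is.matrix(scheds)) scheds <- asplit(scheds, 1)
      l <- evaluate_schedules_cached(ev, scheds)
      base <- ev$env$baselines
      disc_ly <- disc_cost <- numeric(length(scheds))
      for (i in seq_along(scheds)) {
        arm <- lapply(seq_along(base), function(r)
          eval_schedules(ev$env$cohorts[[r]], list(scheds[[i]]),
                         ev$env$screen_seeds[r])[1, ])
        disc_ly[i] <- stats::median(vapply(seq_along(base), function(r)
          arm[[r]]["disc_life_years"] - base[[r]]["disc_life_years"],
          numeric(1)))
        disc_cost[i] <- stats::median(vapply(seq_along(base), function(r)
          arm[[r]]["disc_cost"] - base[[r]]["disc_cost"], numeric(1)))
      }
      lad <- icer_ladder(data.frame(
        label = vapply(scheds, function(s) paste(s, collapse = ","), ""),
        disc_cost = disc_cost, disc_ly = disc_ly))
      utils::write.csv(lad, file.path(out_dir, "icer_ladder.csv"),
                       row.names = FALSE)
      list(ladder = lad, landscape = l)
    },
    stop_bad("unknown experiment kind: ", kind))
  manifest <- list(
    kind = kind, population = n, replicates = reps, base_seed = seed,
    replicate_seeds = lapply(seq_len(reps), function(r)
      list(history = derive_seed(seed, r, 1),
           screening = derive_seed(seed, r, 2))),
    scenario = config$scenario %||% "default_us",
    generator = "mt19937-64 (history) + splitmix64 (screening overlay)",
    package_version = as.character(utils::packageVersion("crcscreen")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
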