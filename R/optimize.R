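# Schedule-space search: exhaustive enumeration with Kung's non-dominated
# filter for 1-2 colonoscopies, and an archive-based ant-colony style
# mixed-integer metaheuristic for 3-4.

#' Enumerate all valid screening schedules with k colonoscopies
#'
#' @param k number of colonoscopies (0-4)
#' @param min_age,max_age,min_gap schedule constraints (years)
#' @return matrix with k columns (0 rows if infeasible; one zero-column row
#'   for k = 0), rows in lexicographic order
#' @export
enumerate_schedules <- function(k, min_age = SCHEDULE_MIN_AGE,
                                max_age = SCHEDULE_MAX_AGE,
                                min_gap = SCHEDULE_MIN_GAP) {
  if (k < 0 || k > SCHEDULE_MAX_K) stop_bad("k must be in 0..4")
  if (k == 0) return(matrix(numeric(0), 1, 0))
  if (min_age + (k - 1) * min_gap > max_age)
    return(matrix(numeric(0), 0, k))
  # bijection with strictly increasing tuples: c_i = a_i - (i-1)*(min_gap-1)
  # ranges over k-subsets of min_age .. max_age - (k-1)*(min_gap-1)
  hi <- max_age - (k - 1) * (min_gap - 1)
  combs <- utils::combn(min_age:hi, k)
  m <- t(combs + (seq_len(k) - 1) * (min_gap - 1))
  m[order_lex(m), , drop = FALSE]
}

order_lex <- function(m) do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))

# deterministic small-integer seed derivation (all arithmetic exact in
# doubles, result < 2^31)
derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + k * 12345 + 1) %% 2147483647
  s + 1
}

#' Build a cached paired-arm schedule evaluator
#'
#' The evaluator simulates `replicates` independent cohorts once (seeds
#' derived from `seed`), evaluates the no-screening arm in each, and then
#' scores any schedule by the four objective reductions against the paired
#' baseline under common random numbers. Each schedule's objectives are the
#' medians across replicates; results are cached so a schedule is never
#' simulated twice.
#'
#' @param bundle a `crc_bundle`
#' @param n persons per replicate arm
#' @param replicates paired replicates per schedule
#' @param seed base seed; replicate history and screening seeds derive from
#'   it deterministically
#' @param sex_fraction_male cohort sex mix
#' @return an object of class `crc_evaluator`; call
#'   `evaluate_schedules_cached(ev, schedules)` or `ev$evaluate(schedules)`
#' @export
make_evaluator <- function(bundle, n = 2e4, replicates = 3, seed = 1,
                           sex_fraction_male = 0.5) {
  env <- new.env(parent = emptyenv())
  env$bundle <- bundle
  env$n <- n
  env$replicates <- replicates
  env$seed <- seed
  env$cohorts <- lapply(seq_len(replicates), function(r)
    init_cohort(n, sex_fraction_male, bundle, derive_seed(seed, r, 1)))
  env$screen_seeds <- vapply(seq_len(replicates), function(r)
    derive_seed(seed, r, 2), numeric(1))
  env$baselines <- lapply(seq_len(replicates), function(r)
    eval_schedules(env$cohorts[[r]], list(integer(0)),
                   env$screen_seeds[r])[1, ])
  env$cache <- new.env(parent = emptyenv())
  env$n_evaluations <- 0L
  ev <- list(env = env,
             evaluate = function(schedules)
               evaluate_schedules_cached(structure(list(env = env),
                                                   class = "crc_evaluator"),
                                         schedules))
  class(ev) <- "crc_evaluator"
  ev
}

#' Evaluator backed by an analytic objective function (toy landscapes)
#'
#' Used to test the search machinery against known optima without running
#' the simulator: `fun(ages)` must return the four objective values (or one
#' value, recycled).
#'
#' @param fun function of an integer age vector
#' @return a `crc_evaluator`
#' @export
toy_evaluator <- function(fun) {
  env <- new.env(parent = emptyenv())
  env$objective_fun <- fun
  env$cache <- new.env(parent = emptyenv())
  env$n_evaluations <- 0L
  env$replicates <- 1L
  ev <- list(env = env)
  class(ev) <- "crc_evaluator"
  ev
}

sched_key <- function(ages) paste(ages, collapse = "_")

#' Evaluate schedules through a cached evaluator
#'
#' @param ev a `crc_evaluator`
#' @param schedules list of integer age vectors, or a matrix (rows =
#'   schedules, NA padding allowed)
#' @return data frame: schedule ages (`age1`..), the four objective medians,
#'   ancillary medians (`lyg_per_1000`, `colonoscopies_per_1000`, ...), and
#'   a `key` column; attribute `per_replicate` holds the objective arrays
#' @export
evaluate_schedules_cached <- function(ev, schedules) {
  env <- ev$env
  m <- schedule_matrix(schedules)
  keys <- apply(m, 1, function(r) sched_key(r[!is.na(r)]))
  todo <- !vapply(keys, function(k) !is.null(env$cache[[k]]), logical(1))
  if (any(todo) && !is.null(env$objective_fun)) {
    # analytic objective (testing/toy landscapes): no simulation
    idx <- which(todo & !duplicated(keys))
    for (j in idx) {
      ages <- m[j, !is.na(m[j, ])]
      obj <- env$objective_fun(ages)
      if (length(obj) < 4) obj <- rep_len(obj, 4)
      names(obj) <- OBJECTIVES
      aux <- c(lyg_per_1000 = NA_real_, dlyg_per_1000 = NA_real_,
               colonoscopies_per_1000 = NA_real_,
               colonoscopies_per_lyg = NA_real_,
               colonoscopies_per_case_prevented = NA_real_)
      env$cache[[keys[j]]] <- list(median = c(obj, aux),
                                   reps = matrix(c(obj, aux), 1,
                                                 dimnames = list(NULL, c(names(obj), names(aux)))))
      env$n_evaluations <- env$n_evaluations + 1L
    }
    todo[] <- FALSE
  }
  if (any(todo)) {
    idx <- which(todo & !duplicated(keys))
    sub <- m[idx, , drop = FALSE]
    per_rep <- lapply(seq_len(env$replicates), function(r)
      eval_schedules(env$cohorts[[r]], sub, env$screen_seeds[r]))
    env$n_evaluations <- env$n_evaluations + length(idx) * env$replicates
    for (j in seq_along(idx)) {
      key <- keys[idx[j]]
      reps <- lapply(seq_len(env$replicates), function(r) {
        row <- per_rep[[r]][j, ]
        obj <- compute_objectives(row, env$baselines[[r]])
        aux <- summary_metrics(row, env$baselines[[r]], env$n)
        c(obj, aux)
      })
      repm <- do.call(rbind, reps)
      env$cache[[key]] <- list(median = apply(repm, 2, stats::median),
                               reps = repm)
    }
  }
  got <- lapply(keys, function(k) env$cache[[k]])
  med <- do.call(rbind, lapply(got, `[[`, "median"))
  ages <- as.data.frame(m)
  if (ncol(ages)) names(ages) <- paste0("age", seq_len(ncol(ages)))
  out <- cbind(ages, as.data.frame(med))
  out$key <- keys
  attr(out, "per_replicate") <- lapply(got, `[[`, "reps")
  out
}

# argmax with earliest-lexicographic tie break on the age columns
argmax_schedule <- function(landscape, objective) {
  v <- landscape[[objective]]
  best <- max(v, na.rm = TRUE)
  cand <- which(v >= best - 1e-12)
  agecols <- grep("^age", names(landscape))
  if (length(cand) > 1 && length(agecols)) {
    sub <- landscape[cand, agecols, drop = FALSE]
    cand <- cand[order_lex(as.matrix(sub))[1]]
  } else cand <- cand[1]
  cand
}

#' Exhaustive schedule search for one or two colonoscopies
#'
#' Evaluates every valid schedule with `k` colonoscopies (or a coarse age
#' grid followed by local refinement) under common random numbers and
#' returns the full landscape plus the per-objective optima. Ties are broken
#' by the lexicographically earliest schedule.
#'
#' @param ev a `crc_evaluator` from [make_evaluator()]
#' @param k 1 or 2 (use [metaheuristic_search()] beyond)
#' @param objectives objective columns to report optima for
#' @param coarse_by evaluate only every `coarse_by`-th age first, then
#'   refine around each coarse optimum (`NULL` = full enumeration)
#' @param refine_radius neighborhood half-width (years) for refinement
#' @return list with `landscape` (data frame) and `best` (named list of
#'   one-row data frames per objective)
#' @export
brute_force_optimize <- function(ev, k, objectives = OBJECTIVES,
                                 coarse_by = NULL, refine_radius = 3) {
  if (k > 2) stop_bad("brute force is restricted to k <= 2; use the metaheuristic")
  objectives <- vapply(objectives, resolve_objective, character(1))
  full <- enumerate_schedules(k)
  grid <- full
  if (!is.null(coarse_by) && k > 0) {
    keep <- rep(TRUE, nrow(full))
    for (j in seq_len(ncol(full)))
      keep <- keep & ((full[, j] - SCHEDULE_MIN_AGE) %% coarse_by == 0)
    grid <- full[keep, , drop = FALSE]
  }
  land <- evaluate_schedules_cached(ev, grid)
  if (!is.null(coarse_by) && k > 0) {
    # refine around each objective's coarse optimum
    extra <- list()
    for (obj in objectives) {
      ctr <- as.numeric(land[argmax_schedule(land, obj),
                             grep("^age", names(land))])
      nb <- neighborhood_schedules(ctr, refine_radius)
      extra <- c(extra, nb)
    }
    if (length(extra)) {
      land2 <- evaluate_schedules_cached(ev, unique_schedules(extra))
      land <- rbind_landscape(land, land2)
    }
  }
  best <- lapply(objectives, function(obj) land[argmax_schedule(land, obj), ])
  names(best) <- objectives
  list(landscape = land, best = best)
}

unique_schedules <- function(lst) lst[!duplicated(vapply(lst, sched_key, ""))]

rbind_landscape <- function(a, b) {
  out <- rbind(a, b)
  pr <- c(attr(a, "per_replicate"), attr(b, "per_replicate"))
  keep <- !duplicated(out$key)
  out2 <- out[keep, , drop = FALSE]
  attr(out2, "per_replicate") <- pr[keep]
  out2
}

# all valid schedules within +/- radius years of `center` (componentwise)
neighborhood_schedules <- function(center, radius = 3) {
  k <- length(center)
  offs <- expand.grid(rep(list(-radius:radius), k))
  out <- list()
  for (i in seq_len(nrow(offs))) {
    s <- sort(center + as.numeric(offs[i, ]))
    ok <- all(s >= SCHEDULE_MIN_AGE & s <= SCHEDULE_MAX_AGE) &&
      (k < 2 || all(diff(s) >= SCHEDULE_MIN_GAP))
    if (ok) out[[length(out) + 1]] <- s
  }
  unique_schedules(out)
}

#' Kung's non-dominated (maxima) filter
#'
#' Exact divide-and-conquer maxima-of-a-vector-set algorithm: returns the
#' indices of points not dominated by any other under componentwise `>=`
#' with at least one strict `>` (maximization in every column). Duplicates
#' of a retained point are all retained.
#'
#' @param points numeric matrix, one row per point
#' @return integer vector of row indices of the non-dominated set
#' @export
kung_front <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(integer(0))
  ord <- do.call(order, c(lapply(seq_len(ncol(points)),
                                 function(j) -points[, j])))
  dominates <- function(a, b) all(a >= b) && any(a > b)
  rec <- function(idx) {
    if (length(idx) <= 1) return(idx)
    half <- ceiling(length(idx) / 2)
    r <- rec(idx[seq_len(half)])
    s <- rec(idx[(half + 1):length(idx)])
    keep <- vapply(s, function(i) {
      for (j in r) if (dominates(points[j, ], points[i, ])) return(FALSE)
      TRUE
    }, logical(1))
    c(r, s[keep])
  }
  sort(rec(ord))
}

#' Archive-based mixed-integer multi-objective metaheuristic
#'
#' Stand-in for a distributed ant-colony mixed-integer solver: keeps a
#' non-dominated archive over the four objectives, proposes new integer age
#' vectors by jittering archive members with a shrinking discrete kernel
#' (plus fresh random restarts), repairs proposals to the valid region
#' (ages in 20-90, 5-year gaps), and evaluates them through the cached
#' paired-arm evaluator. Stochastic but reproducible under `seed`; no
#' optimality guarantee.
#'
#' @param ev a `crc_evaluator`
#' @param k number of colonoscopies (any k, intended for 3-4)
#' @param iterations proposal generations after the initial population
#' @param population proposals per generation
#' @param seed seed for the proposal RNG
#' @param sd_init,sd_final kernel width (years) at the first / last iteration
#' @return list with `archive` (non-dominated landscape rows), `best`
#'   (per-objective rows), `history` (archive snapshots), `n_evaluated`
#' @export
metaheuristic_search <- function(ev, k, iterations = 15, population = 20,
                                 seed = 1, sd_init = 8, sd_final = 1) {
  if (iterations < 0 || population < 1) stop_bad("invalid search budget")
  set.seed(derive_seed(seed, 97))
  random_schedule <- function() repair_schedule(
    sort(sample(SCHEDULE_MIN_AGE:SCHEDULE_MAX_AGE, k)))
  # structured starts: equally spaced schedules spanning the feasible
  # (start, gap) plane; the optima of this problem family sit close to
  # this ridge, and covering it avoids early stagnation of the archive
  lattice <- list()
  if (k >= 2) {
    for (g in seq(SCHEDULE_MIN_GAP, floor((SCHEDULE_MAX_AGE - SCHEDULE_MIN_AGE) /
                                            (k - 1)), by = 2)) {
      starts <- seq(SCHEDULE_MIN_AGE, SCHEDULE_MAX_AGE - (k - 1) * g, by = 4)
      for (a in starts)
        lattice[[length(lattice) + 1]] <- a + (0:(k - 1)) * g
    }
  } else lattice <- lapply(seq(20, 90, by = 4), identity)
  lattice <- unique_schedules(lattice)
  n_lat <- min(length(lattice), max(2, population %/% 2))
  pop <- c(lattice[sort(sample.int(length(lattice), n_lat))],
           lapply(seq_len(population - n_lat), function(i) random_schedule()))
  land <- evaluate_schedules_cached(ev, unique_schedules(pop))
  objm <- function(l) as.matrix(l[, OBJECTIVES, drop = FALSE])
  arch <- land[kung_front(objm(land)), , drop = FALSE]
  history <- list(arch)
  for (it in seq_len(iterations)) {
    sd_now <- sd_init + (sd_final - sd_init) * (it - 1) / max(1, iterations - 1)
    props <- lapply(seq_len(population), function(i) {
      u <- stats::runif(1)
      if (u < 0.2 || nrow(arch) == 0) return(random_schedule())
      base <- as.numeric(arch[sample.int(nrow(arch), 1),
                              grep("^age", names(arch))])
      if (u < 0.45) {
        # translate the whole schedule along the ridge of near-equal value
        d <- sample(c(-6:-1, 1:6), 1)
        repair_schedule(base + d)
      } else {
        repair_schedule(base + round(stats::rnorm(k, 0, sd_now)))
      }
    })
    land_new <- evaluate_schedules_cached(ev, unique_schedules(props))
    pool <- rbind(arch[, names(land_new)], land_new)
    pool <- pool[!duplicated(pool$key), , drop = FALSE]
    arch <- pool[kung_front(objm(pool)), , drop = FALSE]
    history[[length(history) + 1]] <- arch
  }
  best <- lapply(OBJECTIVES, function(obj) arch[argmax_schedule(arch, obj), ])
  names(best) <- OBJECTIVES
  list(archive = arch, best = best, history = history,
       n_evaluated = ev$env$n_evaluations)
}

#' Repair an integer age vector to a valid schedule
#'
#' Sorts, clamps to the age range and pushes ages apart (forward then
#' backward) until all gaps are at least 5 years; always returns a valid
#' schedule for k <= 4.
#'
#' @param ages integer ages
#' @export
repair_schedule <- function(ages) {
  a <- sort(round(ages))
  k <- length(a)
  a <- pmin(pmax(a, SCHEDULE_MIN_AGE), SCHEDULE_MAX_AGE)
  if (k > 1) {
    for (i in 2:k) a[i] <- max(a[i], a[i - 1] + SCHEDULE_MIN_GAP)
    a[k] <- min(a[k], SCHEDULE_MAX_AGE)
    for (i in (k - 1):1) a[i] <- min(a[i], a[i + 1] - SCHEDULE_MIN_GAP)
    a <- pmax(a, SCHEDULE_MIN_AGE)
    for (i in 2:k) a[i] <- max(a[i], a[i - 1] + SCHEDULE_MIN_GAP) # safety
  }
  as.integer(a)
}

#' Near-optimal region of a landscape
#'
#' Rows achieving at least `frac` of the maximum objective (measured from
#' the maximum towards zero), with the objective-weighted centroid of each
#' age coordinate. The centroid is a much lower-variance location estimate
#' of a flat optimum than the argmax and is what the directional
#' sensitivity checks compare.
#'
#' @param landscape landscape data frame from the evaluator
#' @param objective objective column (alias allowed)
#' @param frac fraction of the maximum defining the region (default 0.95)
#' @return list with `argmax` (row), `region` (rows), and `centroid`
#'   (named numeric, one entry per age column)
#' @export
optimum_region <- function(landscape, objective, frac = 0.95) {
  objective <- resolve_objective(objective)
  v <- landscape[[objective]]
  thr <- max(v, na.rm = TRUE) - (1 - frac) * abs(max(v, na.rm = TRUE))
  region <- landscape[!is.na(v) & v >= thr, , drop = FALSE]
  agecols <- grep("^age", names(landscape), value = TRUE)
  centroid <- vapply(agecols, function(a) mean(region[[a]]), numeric(1))
  amax <- landscape[argmax_schedule(landscape, objective), , drop = FALSE]
  # for a single-age landscape also fit a local parabola in a +/-5-year
  # window around the argmax: its vertex is a low-noise peak-location
  # estimate unaffected by the asymmetric shoulders of the plateau
  vertex <- NA_real_
  if (length(agecols) == 1) {
    near <- abs(landscape[[agecols]] - amax[[agecols]]) <= 5 & !is.na(v)
    if (sum(near) >= 5) {
      x <- landscape[[agecols]][near]
      y <- v[near]
      cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
      if (is.finite(cf[3]) && cf[3] < 0) vertex <- -cf[2] / (2 * cf[3])
    }
    if (!is.finite(vertex)) vertex <- as.numeric(amax[[agecols]])
  }
  list(argmax = amax, region = region, centroid = centroid, vertex = vertex)
}

#' Locally refine a schedule by exhaustive neighborhood search
#'
#' Evaluates every valid schedule within `radius` years (componentwise) of
#' `schedule` and returns the best row for `objective`; used to verify a
#' metaheuristic incumbent.
#'
#' @param ev a `crc_evaluator`
#' @param schedule integer ages
#' @param objective objective column (alias allowed)
#' @param radius neighborhood half-width in years
#' @return one-row landscape data frame of the local optimum
#' @export
refine_schedule <- function(ev, schedule, objective = "dlyl", radius = 3,
                            max_rounds = 1) {
  objective <- resolve_objective(objective)
  cur <- as.numeric(schedule)
  best <- NULL
  for (round in seq_len(max_rounds)) {
    nb <- neighborhood_schedules(cur, radius)
    land <- evaluate_schedules_cached(ev, nb)
    best <- land[argmax_schedule(land, objective), , drop = FALSE]
    nxt <- as.numeric(best[, grep("^age", names(best)), drop = FALSE])
    if (identical(nxt, cur)) break
    cur <- nxt
    radius <- min(radius, 2)  # cheaper follow-up rounds
  }
  best
}

#' Balanced compromise member of a Pareto archive
#'
#' Returns the archive row minimizing the maximum relative shortfall across
#' the four objectives (each objective's shortfall is measured against the
#' best value attained in the archive, scaled by its magnitude).
#'
#' @param archive landscape data frame (rows non-dominated)
#' @export
balanced_solution <- function(archive) {
  m <- as.matrix(archive[, OBJECTIVES, drop = FALSE])
  best <- apply(m, 2, max)
  shortfall <- sweep(-m, 2, best, "+")
  rel <- sweep(shortfall, 2, pmax(abs(best), 1e-9), "/")
  archive[which.min(apply(rel, 1, max)), , drop = FALSE]
}
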