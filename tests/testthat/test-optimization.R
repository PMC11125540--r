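# schedule search: enumeration, brute force on analytic landscapes, Kung's
# front vs the O(n^2) oracle, metaheuristic behavior and repair

test_that("enumeration counts and ordering", {
  expect_identical(nrow(enumerate_schedules(0)), 1L)
  expect_identical(ncol(enumerate_schedules(0)), 0L)
  e1 <- enumerate_schedules(1)
  expect_identical(nrow(e1), 71L)
  expect_identical(e1[, 1], as.numeric(20:90))
  e2 <- enumerate_schedules(2)
  expect_identical(nrow(e2), 2211L)        # sum_{j=1}^{66} j
  expect_true(all(e2[, 2] - e2[, 1] >= 5))
  # lexicographic order
  expect_true(all(diff(e2[, 1]) >= 0))
  # infeasible constraints give an empty list
  expect_identical(nrow(enumerate_schedules(4, min_age = 80, max_age = 90,
                                            min_gap = 5)), 0L)
  expect_error(enumerate_schedules(5), "0..4")
})

test_that("brute force finds the peak of a unimodal toy objective and tie-breaks", {
  ev <- toy_evaluator(function(a) rep(-(a[1] - 57)^2, 4))
  r <- brute_force_optimize(ev, 1)
  expect_identical(r$best[[1]]$age1, 57)
  expect_error(brute_force_optimize(ev, 3), "k <= 2")

  # constant objective: lexicographically earliest schedule wins
  evc <- toy_evaluator(function(a) rep(1, 4))
  rc <- brute_force_optimize(evc, 2)
  expect_identical(c(rc$best[[1]]$age1, rc$best[[1]]$age2), c(20, 25))
})

test_that("coarse grid plus refinement matches full enumeration on smooth toys", {
  f <- function(a) rep(-(a[1] - 57)^2 - (a[2] - 71)^2, 4)
  full <- brute_force_optimize(toy_evaluator(f), 2)
  coarse <- brute_force_optimize(toy_evaluator(f), 2, coarse_by = 2,
                                 refine_radius = 3)
  expect_identical(c(full$best[[1]]$age1, full$best[[1]]$age2),
                   c(coarse$best[[1]]$age1, coarse$best[[1]]$age2))
})

test_that("kung_front: hand example, single point, duplicates, oracle equivalence", {
  expect_identical(kung_front(matrix(1:4, 1)), 1L)
  pts <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0.5, 0.5, 0.5, 0.5),
               c(0, 0, 0, 0))
  expect_identical(kung_front(pts), c(1L, 2L, 3L))
  # duplicates of a kept point are all retained
  dup <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_identical(kung_front(dup), c(1L, 2L))
  expect_identical(kung_front(matrix(numeric(0), 0, 4)), integer(0))

  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(runif(500 * 4), 500, 4)
    got <- kung_front(m)
    want <- pairwise_front(m)
    expect_identical(got, want)
    # every excluded point is dominated by some kept point
    excl <- setdiff(seq_len(nrow(m)), got)
    for (i in excl[seq_len(min(20, length(excl)))]) {
      dom <- any(vapply(got, function(j)
        all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ]), logical(1)))
      expect_true(dom)
    }
  }
})

test_that("repair always yields valid schedules (property over random proposals)", {
  set.seed(8)
  for (i in 1:300) {
    k <- sample(1:4, 1)
    raw <- sample(0:120, k, replace = TRUE)
    s <- repair_schedule(raw)
    expect_silent(validate_schedule(s))
  }
})

test_that("metaheuristic: zero iterations, toy-landscape equivalence, archive monotonicity", {
  f <- function(a) c(-(a[1] - 40)^2 - (a[2] - 60)^2,
                     -(a[1] - 60)^2 - (a[2] - 80)^2,
                     -(a[1] - 50)^2 - (a[2] - 70)^2,
                     -(a[1] - 45)^2 - (a[2] - 65)^2)
  ev0 <- toy_evaluator(f)
  r0 <- metaheuristic_search(ev0, 2, iterations = 0, population = 10, seed = 1)
  expect_lte(ev0$env$n_evaluations, 10)
  expect_gt(nrow(r0$archive), 0)

  # exact invariant: the archive is the Kung front of everything evaluated
  f1 <- function(a) c(-(a - 40)^2, -(a - 60)^2, -(a - 50)^2, -(a - 45)^2)
  ev1 <- toy_evaluator(f1)
  r1 <- metaheuristic_search(ev1, 1, iterations = 40, population = 30, seed = 2)
  seen <- ls(ev1$env$cache)
  seen_m <- t(vapply(seen, function(k) f1(as.numeric(k)), numeric(4)))
  want_keys <- sort(seen[kung_front(seen_m)])
  expect_identical(sort(r1$archive$key), want_keys)

  # with a budget covering the (71-point) space, the archive and the
  # per-objective optima match the brute-force landscape exactly
  bf <- brute_force_optimize(toy_evaluator(f1), 1)
  front_keys <- sort(bf$landscape$key[kung_front(
    as.matrix(bf$landscape[, OBJECTIVES]))])
  for (obj in OBJECTIVES)
    expect_identical(r1$best[[obj]]$age1, bf$best[[obj]]$age1)
  expect_identical(sort(r1$archive$key), front_keys)

  # archive never degrades: every earlier archive point is weakly dominated
  # by some member of every later archive
  hist <- r1$history
  objm <- function(d) as.matrix(d[, OBJECTIVES])
  for (t in seq_len(length(hist) - 1)) {
    old <- objm(hist[[t]])
    new <- objm(hist[[t + 1]])
    for (i in seq_len(nrow(old))) {
      covered <- any(vapply(seq_len(nrow(new)), function(j)
        all(new[j, ] >= old[i, ] - 1e-12), logical(1)))
      expect_true(covered)
    }
  }
})

test_that("balanced solution minimizes the maximum relative shortfall", {
  arch <- data.frame(age1 = c(50, 55, 60),
                     discounted_lyl_reduction_pct = c(40, 38, 30),
                     incidence_reduction_pct = c(30, 38, 40),
                     mortality_reduction_pct = c(35, 38, 39),
                     cost_reduction_pct = c(20, 19, 20))
  bal <- balanced_solution(arch)
  expect_identical(bal$age1, 55)
})

test_that("landscape is invariant to evaluation order under CRN", {
  b <- default_bundle()
  ev1 <- make_evaluator(b, n = 3000, replicates = 2, seed = 33)
  ev2 <- make_evaluator(b, n = 3000, replicates = 2, seed = 33)
  s <- list(50, 60, 70, 55)
  l1 <- evaluate_schedules_cached(ev1, s)
  l2 <- evaluate_schedules_cached(ev2, rev(s))
  m1 <- l1[order(l1$age1), OBJECTIVES]
  m2 <- l2[order(l2$age1), OBJECTIVES]
  expect_equal(m1, m2, ignore_attr = TRUE)
})
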