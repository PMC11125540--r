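# natural-history engine: determinism, distributional checks, Markov oracle,
# CRN contract, agreement between the compiled and the R stepping engines

test_that("init_cohort is deterministic and validates n", {
  b <- default_bundle()
  c1 <- init_cohort(200, 0.5, b, seed = 42)
  c2 <- init_cohort(200, 0.5, b, seed = 42)
  expect_identical(cohort_persons(c1), cohort_persons(c2))
  expect_identical(cohort_lesions(c1), cohort_lesions(c2))
  c3 <- init_cohort(200, 0.5, b, seed = 43)
  expect_false(identical(cohort_persons(c1)$other_cause_death_q,
                         cohort_persons(c3)$other_cause_death_q))
  expect_error(init_cohort(0, 0.5, b, 1), "positive")
})

test_that("risk multipliers: degenerate at 1 and mean 1 at scale", {
  b <- default_bundle()
  b$nh$risk_sdlog <- 0
  co <- init_cohort(500, 0.5, b, seed = 1)
  expect_true(all(cohort_persons(co)$risk_multiplier == 1))

  b$nh$risk_sdlog <- 0.65
  co2 <- init_cohort(1e5, 0.5, b, seed = 1)
  r <- cohort_persons(co2)$risk_multiplier
  se <- sd(r) / sqrt(length(r))
  expect_within(mean(r), 1, 3 * se)
})

test_that("step_quarter: zero rates leave the person unchanged except age", {
  b <- null_bundle()
  b$life_table <- no_death_life_table()
  p <- new_person(1, 0, 1)
  set.seed(1)
  for (i in 1:8) p <- step_quarter(p, b)
  expect_identical(p$age_q, 8L)
  expect_true(p$alive)
  expect_length(p$ad_stage, 0)
  expect_length(p$ca_stage, 0)
  p$alive <- FALSE
  expect_error(step_quarter(p, b), "dead")
})

test_that("adenoma counts are Poisson under constant hazard with progression off", {
  h <- 0.002
  b <- with_life_table(constant_adenoma_bundle(h), no_death_life_table())
  n <- 2e4
  co <- init_cohort(n, 0.5, b, seed = 9)
  counts <- cohort_persons(co)$n_adenomas
  # initiation runs over quarters 0..399 -> Binomial(400, h) ~ Poisson(0.8)
  lambda <- 400 * h
  expect_within(mean(counts), lambda, 4 * sqrt(lambda / n))
  for (k in 0:3) {
    p_theory <- dbinom(k, 400, h)
    p_emp <- mean(counts == k)
    expect_within(p_emp, p_theory, 4 * sqrt(p_theory * (1 - p_theory) / n) + 1e-4)
  }
})

test_that("blocked chain: transformation only at stage 6 with no progression", {
  b <- constant_adenoma_bundle(0.01, prog = rep(0, 6),
                               cancer = c(0, 0, 0, 0, 0, 0.05))
  co <- init_cohort(5000, 0.5, b, seed = 2)
  expect_identical(nrow(cohort_lesions(co)$cancers), 0L)
})

test_that("CRC death scheduling: survival fractions and the 20-quarter bound", {
  b <- default_bundle()
  # every cancer from the default run respects the 5-year bound
  co <- init_cohort(3e4, 0.5, b, seed = 4)
  rec <- run_cohort(co, keep_persons = TRUE)$persons
  crc <- rec[rec$cause == 1, ]
  les <- cohort_lesions(co)$cancers
  # death quarter never exceeds onset + 20 for the diagnosed cancer
  key <- match(paste(crc$id, crc$dx_q), paste(les$person, les$sympt_q))
  onset <- les$onset_q[key]
  ok <- !is.na(onset)
  expect_true(all(crc$death_q[ok] - onset[ok] <= 20))

  # stage-specific death fraction: survival 0.2 -> 80% die (binomial check),
  # via the R-level scheduler
  b$nh$surv5 <- c(0.2, 0.2, 0.2, 0.2)
  set.seed(11)
  deaths <- replicate(4000, !is.na(schedule_crc_death(100, 104, 4, b$nh)))
  expect_within(mean(deaths), 0.8, 4 * sqrt(0.8 * 0.2 / 4000))

  # survival 1 everywhere -> nobody dies of CRC
  b$nh$surv5 <- rep(1, 4)
  set.seed(12)
  expect_true(all(is.na(replicate(500, schedule_crc_death(100, 104, 3, b$nh)))))
})

test_that("zero disease rates reproduce the life table exactly", {
  b <- null_bundle()
  n <- 5e4
  co <- init_cohort(n, 1, b, seed = 6)   # all male
  rec <- run_cohort(co, keep_persons = TRUE)$persons
  expect_true(all(rec$cause == 0))
  expect_identical(rec$death_q, rec$other_cause_death_q)
  # empirical death-quarter distribution matches the life-table pmf
  pmf <- life_table_death_pmf(b$life_table, 0)
  mean_theory <- sum((0:400) * pmf)
  sd_theory <- sqrt(sum((0:400)^2 * pmf) - mean_theory^2)
  expect_within(mean(rec$death_q), mean_theory, 4 * sd_theory / sqrt(n))
})

test_that("CRN contract: undetectable screening reproduces no-screening person-for-person", {
  b <- default_bundle()
  b$colo$sens_adenoma <- rep(0, 6)
  b$colo$sens_cancer <- 0
  b$colo$compl_prob <- rep(0, 3)
  co <- init_cohort(2e4, 0.5, b, seed = 8)
  base <- run_cohort(co, NULL, screen_seed = 5, keep_persons = TRUE)$persons
  scr <- run_cohort(co, c(50, 60, 70), screen_seed = 5, keep_persons = TRUE)$persons
  expect_identical(scr$death_q, base$death_q)
  expect_identical(scr$cause, base$cause)
  expect_identical(scr$dx_q, base$dx_q)
  expect_gt(sum(scr$colos_screening), 0)
  expect_identical(sum(base$colos_screening), 0L)
})

test_that("origin is exclusive: adenoma pathway off implies direct-path only, and conversely", {
  b <- default_bundle()
  b$nh$cancer_p <- rep(0, 6)
  co <- init_cohort(2e4, 0.5, b, seed = 10)
  ca <- cohort_lesions(co)$cancers
  expect_gt(nrow(ca), 0)
  expect_true(all(ca$origin == 1))

  b2 <- default_bundle()
  b2$nh$direct_rate_m[] <- 0
  b2$nh$direct_rate_f[] <- 0
  co2 <- init_cohort(2e4, 0.5, b2, seed = 10)
  ca2 <- cohort_lesions(co2)$cancers
  expect_gt(nrow(ca2), 0)
  expect_true(all(ca2$origin == 0))
})

test_that("monotone hazard: doubling initiation does not decrease incidence", {
  b <- default_bundle()
  n <- 5e4
  co1 <- init_cohort(n, 0.5, b, seed = 13)
  inc1 <- run_cohort(co1)$outcomes[["cases"]]
  b2 <- scale_bundle(b, "adenoma_risk", 2)
  co2 <- init_cohort(n, 0.5, b2, seed = 13)
  inc2 <- run_cohort(co2)$outcomes[["cases"]]
  expect_gt(inc2, inc1 - 3 * sqrt(inc1))
  expect_gt(inc2, inc1)  # at doubling the effect dwarfs MC noise
})

test_that("Markov oracle: adenoma stage occupancy matches matrix powers", {
  # constant rates; the per-quarter transition kernel for one adenoma is
  # cancer with prob c_s else progression with prob p_s
  prog <- c(0.08, 0.06, 0.05, 0.04, 0.03, 0)
  cancer <- c(0.002, 0.004, 0.006, 0.01, 0.02, 0.04)
  b <- with_life_table(constant_adenoma_bundle(0.004, prog, cancer),
                       no_death_life_table())
  co <- init_cohort(3e4, 0.5, b, seed = 14)
  les <- cohort_lesions(co)
  ad <- les$adenomas
  st <- as.matrix(ad[, grep("stage_entry_q", names(ad))])
  M <- matrix(0, 7, 7)  # states: stages 1-6, absorbing cancer
  for (s in 1:6) {
    M[s, 7] <- cancer[s]
    if (s < 6) M[s, s + 1] <- (1 - cancer[s]) * prog[s]
    M[s, s] <- 1 - M[s, 7] - if (s < 6) M[s, s + 1] else 0
  }
  M[7, 7] <- 1  # cancer is absorbing
  occ_at <- function(m) {
    # empirical state distribution m quarters after initiation (uncensored:
    # lesion trajectories are simulated to the horizon regardless of death)
    t_at <- ad$init_q + m
    usable <- t_at <= 300  # avoid the age-100 truncation
    stq <- st[usable, , drop = FALSE]
    tr <- ad$transform_q[usable]
    tt <- t_at[usable]
    stage <- integer(length(tt))
    for (s in 1:6) stage[!is.na(stq[, s]) & stq[, s] <= tt] <- s
    stage[!is.na(tr) & tr <= tt] <- 7L
    tabulate(stage, 7) / length(stage)
  }
  for (m in c(8, 40, 120)) {
    theory <- as.numeric(c(1, rep(0, 6)) %*% matpow(M, m))
    emp <- occ_at(m)
    n_eff <- sum(ad$init_q + m <= 300)
    for (s in 1:7) {
      se <- sqrt(max(theory[s] * (1 - theory[s]), 1e-6) / n_eff)
      expect_within(emp[s], theory[s], 3.5 * se + 1e-3)
    }
  }
})

test_that("compiled engine and R stepping engine agree distributionally", {
  b <- default_bundle()
  n_r <- 1500
  ref <- reference_run_cohort(n_r, b, schedule = NULL, seed = 21)
  n_c <- 3e4
  co <- init_cohort(n_c, 0.5, b, seed = 22)
  fast <- run_cohort(co, keep_persons = TRUE)$persons

  # lifetime incidence
  p_ref <- mean(!is.na(ref$dx_q))
  p_fast <- mean(!is.na(fast$dx_q))
  se <- sqrt(p_fast * (1 - p_fast) / n_r + p_fast * (1 - p_fast) / n_c)
  expect_within(p_ref, p_fast, 3.5 * se)
  # mean age at death
  se_d <- sd(ref$death_q) / sqrt(n_r)
  expect_within(mean(ref$death_q), mean(fast$death_q), 3.5 * se_d)
  # mean lifetime adenoma count
  se_a <- sd(ref$n_adenomas) / sqrt(n_r)
  expect_within(mean(ref$n_adenomas), mean(fast$n_adenomas), 3.5 * se_a)
})

test_that("engines agree under screening too", {
  b <- default_bundle()
  sched <- c(55, 65)
  ref <- reference_run_cohort(1200, b, schedule = sched, seed = 31)
  co <- init_cohort(3e4, 0.5, b, seed = 32)
  fast <- run_cohort(co, sched, keep_persons = TRUE)$persons
  p_ref <- mean(!is.na(ref$dx_q))
  p_fast <- mean(!is.na(fast$dx_q))
  se <- sqrt(p_ref * (1 - p_ref) / 1200)
  expect_within(p_ref, p_fast, 3.5 * se + 1e-3)
  # screening colonoscopy volume per person
  m_ref <- mean(ref$colos_screening)
  m_fast <- mean(fast$colos_screening)
  expect_within(m_ref, m_fast, 3.5 * sd(ref$colos_screening) / sqrt(1200))
})
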