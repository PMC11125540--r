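# screening: schedule validation, colonoscopy mechanics, surveillance,
# adherence scaling, and screening-effect invariants

test_that("validate_schedule enforces the constraint set", {
  expect_identical(validate_schedule(c(50, 60, 70))$ages, c(50L, 60L, 70L))
  expect_identical(validate_schedule(integer(0))$ages, integer(0))
  expect_identical(validate_schedule(c(70, 50, 60))$ages, c(50L, 60L, 70L))
  expect_error(validate_schedule(c(50, 52)), "apart")
  expect_error(validate_schedule(19), "lie in")
  expect_error(validate_schedule(91), "lie in")
  expect_error(validate_schedule(c(20, 30, 40, 50, 60)), "at most 4")
  expect_error(validate_schedule(55.5), "integer")
})

test_that("next_surveillance is a pure guideline lookup", {
  g <- surveillance_guideline()
  expect_null(next_surveillance(list(findings_category = "no_adenoma",
                                     age = 60), g))
  expect_identical(next_surveillance(list(findings_category = "1-2_early",
                                          age = 60), g), 5)
  expect_identical(next_surveillance(list(findings_category = ">=3_or_advanced",
                                          age = 60), g), 3)
  expect_null(next_surveillance(list(findings_category = ">=3_or_advanced",
                                     age = 90), g))
  expect_error(next_surveillance(list(findings_category = "weird", age = 50), g),
               "unknown")
})

test_that("perform_colonoscopy: perfect detection removes everything; reach truncates", {
  b <- default_bundle()
  colo_perfect <- b$colo
  colo_perfect$reach <- c(1, 1, 1)
  colo_perfect$sens_adenoma <- rep(1, 6)
  colo_perfect$sens_cancer <- 1
  colo_perfect$compl_prob <- rep(0, 3)
  p <- new_person(1, 0, 1)
  p$ad_stage <- c(1L, 5L); p$ad_loc <- c(0L, 7L)  # cecum and rectum
  p$ad_init <- c(10L, 10L); p$ad_removed <- c(FALSE, FALSE)
  p$ad_transformed <- c(FALSE, FALSE)
  p$age_q <- 220L
  set.seed(1)
  res <- perform_colonoscopy(p, colo_perfect, b$nh)
  expect_true(all(res$person$ad_removed))
  expect_identical(res$result$findings_category, ">=3_or_advanced")

  # reach 0 past the splenic flexure: the cecal lesion is never detected
  colo_short <- colo_perfect
  colo_short$reach <- c(0, 0, 0)
  p2 <- new_person(2, 0, 1)
  p2$ad_stage <- 6L; p2$ad_loc <- 0L; p2$ad_init <- 10L
  p2$ad_removed <- FALSE; p2$ad_transformed <- FALSE
  p2$age_q <- 220L
  set.seed(2)
  for (i in 1:20) {
    r2 <- perform_colonoscopy(p2, colo_short, b$nh)
    expect_false(any(r2$person$ad_removed))
  }
})

test_that("per-lesion detection fraction matches the stage sensitivity (binomial)", {
  b <- default_bundle()
  colo <- b$colo
  colo$reach <- c(1, 1, 1)
  colo$sens_adenoma <- c(0, 0, 0, 0, 0.9, 0)
  colo$compl_prob <- rep(0, 3)
  n <- 2e4
  set.seed(3)
  hits <- vapply(seq_len(n), function(i) {
    p <- new_person(i, 0, 1)
    p$ad_stage <- 5L; p$ad_loc <- 6L; p$ad_init <- 10L
    p$ad_removed <- FALSE; p$ad_transformed <- FALSE
    p$age_q <- 220L
    perform_colonoscopy(p, colo, b$nh)$person$ad_removed
  }, logical(1))
  expect_within(mean(hits), 0.9, 4 * sqrt(0.9 * 0.1 / n))
})

test_that("adherence 0 reproduces no screening; attendance scales linearly", {
  b <- default_bundle()
  b$colo$adherence <- 0
  co <- init_cohort(2e4, 0.5, b, seed = 15)
  base <- run_cohort(co, NULL, screen_seed = 2)$outcomes
  scr <- run_cohort(co, c(55, 65), screen_seed = 2)$outcomes
  expect_identical(scr[["colos_screen"]], 0)
  expect_identical(scr[["cases"]], base[["cases"]])
  expect_identical(scr[["lyl"]], base[["lyl"]])
  expect_gt(scr[["invitations"]], 0)

  # linear scaling of expected screening attendances in adherence
  counts <- vapply(c(0.25, 0.5, 1), function(a) {
    bb <- default_bundle()
    bb$colo$adherence <- a
    cc <- init_cohort(2e4, 0.5, bb, seed = 15)
    run_cohort(cc, c(55, 65), screen_seed = 2)$outcomes[["colos_screen"]]
  }, numeric(1))
  expect_within(counts[1] / counts[3], 0.25, 0.03)
  expect_within(counts[2] / counts[3], 0.5, 0.03)
  # colonoscopies never exceed the invitation + surveillance + diagnostic bound
  out <- run_cohort(init_cohort(1e4, 0.5, default_bundle(), seed = 15),
                    c(55, 65), screen_seed = 2)$outcomes
  expect_lte(out[["colos_screen"]], out[["invitations"]])
})

test_that("single screening exam lowers CRC incidence (paired arms)", {
  b <- default_bundle()
  co <- init_cohort(5e4, 0.5, b, seed = 16)
  base <- run_cohort(co, NULL, screen_seed = 3)$outcomes
  scr <- run_cohort(co, 55, screen_seed = 3)$outcomes
  expect_lt(scr[["cases"]], base[["cases"]] - 3 * sqrt(base[["cases"]]))
  # screening attendance matches the alive & undiagnosed fraction at 55
  rec <- run_cohort(co, NULL, keep_persons = TRUE)$persons
  eligible <- sum(rec$death_q >= 220 & (is.na(rec$dx_q) | rec$dx_q > 220))
  expect_within(scr[["colos_screen"]], eligible, 0.002 * eligible + 5)
})

test_that("no ghost cancers: removing an adenoma removes its future cancer", {
  b <- default_bundle()
  b$colo$sens_adenoma <- rep(1, 6)
  b$colo$sens_cancer <- 1
  b$colo$reach <- c(1, 1, 1)
  b$nh$direct_rate_m[] <- 0
  b$nh$direct_rate_f[] <- 0
  co <- init_cohort(2e4, 0.5, b, seed = 17)
  les <- cohort_lesions(co)
  base <- run_cohort(co, NULL, keep_persons = TRUE)$persons
  scr <- run_cohort(co, c(50, 60, 70), keep_persons = TRUE)$persons
  # any person whose every potential cancer stems from an adenoma that was
  # present (pre-malignant) at an attended exam can no longer be a case
  removed_cases <- !is.na(base$dx_q) & is.na(scr$dx_q)
  expect_gt(sum(removed_cases), 0)
  expect_lt(sum(!is.na(scr$dx_q)), sum(!is.na(base$dx_q)))
  # nobody becomes a case without a potential cancer in their history
  has_cancer <- base$n_cancers > 0
  expect_true(all(has_cancer[!is.na(scr$dx_q)]))
})

test_that("intensive screening bound: 5-yearly perfect exams nearly eliminate incidence", {
  b <- default_bundle()
  b$colo$sens_adenoma <- rep(1, 6)
  b$colo$sens_cancer <- 1
  b$colo$reach <- c(1, 1, 1)
  b$nh$direct_rate_m[] <- 0
  b$nh$direct_rate_f[] <- 0
  co <- init_cohort(2e4, 0.5, b, seed = 18)
  base <- run_cohort(co, NULL)$outcomes
  # four exams max per schedule: emulate 5-yearly 20-90 via surveillance-free
  # repeated arms is out of contract; instead check the strongest 4-exam
  # schedule plus guideline surveillance
  scr <- eval_schedules(co, list(c(45, 55, 65, 75)))[1, ]
  red <- 100 * (base[["cases"]] - scr[["cases"]]) / base[["cases"]]
  expect_gt(red, 80)
  # and with the dense exam pattern applied through the stepping engine
  # contract (schedule constraint caps at 4), the residual is only fast
  # transitions between exams -- checked on the compiled engine with an
  # unconstrained schedule matrix
  out <- eval_schedules(co, list(seq(20, 90, by = 5)))
  red_dense <- 100 * (base[["cases"]] - out[1, "cases"]) / base[["cases"]]
  expect_gt(red_dense, 95)
})
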