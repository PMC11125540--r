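# outcomes & economics: discounting, cost accrual, objectives, summary
# metrics, ICER

test_that("discount: anchor identity, closed form, zero rate, pre-anchor clamp", {
  expect_equal(discount(100, 20, 0.03, 20), 100)
  expect_equal(discount(100, 30, 0.03, 20), 100 / 1.03^10)
  expect_within(discount(100, 30, 0.03, 20), 74.41, 0.005)
  expect_equal(discount(123.4, 87, 0, 20), 123.4)
  expect_equal(discount(100, 10, 0.03, 20), 100)  # clamped before anchor
})

test_that("discounting is multiplicative and order-independent", {
  set.seed(5)
  amounts <- runif(50, 0, 1000)
  ages <- runif(50, 0, 100)
  a <- sum(discount(amounts, ages))
  b <- sum(vapply(seq_along(amounts),
                  function(i) discount(amounts[i], ages[i]), numeric(1)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("cost accrual: precedence, 5-year cap, and procedure-only records", {
  costs <- cost_params()
  # diagnosis with CRC death 18 months (6 quarters) later: quarters 0-1
  # relative to dx are initial, 2-5 terminal (precedence)
  rec <- list(dx_q = 200, dx_stage = 3, death_q = 206, cause = "crc")
  led <- accrue_costs(rec, costs)
  treat <- led$by_quarter[led$by_quarter$category != "procedure", ]
  expect_identical(nrow(treat), 7L)  # quarters 200..206
  expect_identical(treat$category[treat$quarter <= 201], rep("initial12mo", 2))
  expect_identical(treat$category[treat$quarter >= 203], rep("terminal12mo", 4))
  expect_false("followup" %in% treat$category)

  # survivor 6 years after diagnosis accrues nothing past 20 quarters
  rec2 <- list(dx_q = 200, dx_stage = 1, death_q = 400, cause = "other")
  led2 <- accrue_costs(rec2, costs)
  tq <- led2$by_quarter$quarter[led2$by_quarter$category %in%
                                  c("initial12mo", "followup", "terminal12mo")]
  expect_lte(max(tq), 219)
  expect_identical(sum(led2$by_quarter$category == "death_unrelated"), 1L)

  # no CRC, one colonoscopy: total = colonoscopy cost
  rec3 <- list(dx_q = NA, procedures = data.frame(quarter = 220, cost = 1000))
  expect_equal(accrue_costs(rec3, costs)$cost, 1000)
})

test_that("every post-diagnosis quarter maps to exactly one category (conservation)", {
  costs <- cost_params()
  set.seed(6)
  for (i in 1:50) {
    dx <- sample(100:350, 1)
    death <- dx + sample(0:60, 1)
    cause <- sample(c("crc", "other"), 1)
    led <- accrue_costs(list(dx_q = dx, dx_stage = sample(1:4, 1),
                             death_q = min(death, 400), cause = cause), costs)
    treat <- led$by_quarter[led$by_quarter$category %in%
                              c("initial12mo", "followup", "terminal12mo"), ]
    expect_false(any(duplicated(treat$quarter)))
    expected_q <- dx:min(death, 400, dx + 19)
    expect_identical(as.integer(sort(treat$quarter)), as.integer(expected_q))
  }
})

test_that("engine cost accrual matches the R oracle person by person", {
  b <- default_bundle()
  # strip procedure costs so the totals isolate treatment accrual
  b$costs$colonoscopy_cost <- 0
  b$costs$polypectomy_surcharge <- 0
  b$costs$complication_cost <- rep(0, 3)
  co <- init_cohort(5000, 0.5, b, seed = 19)
  rec <- run_cohort(co, c(55, 65), keep_persons = TRUE)$persons
  cause_chr <- c("other", "crc", "complication")[rec$cause + 1]
  for (i in which(!is.na(rec$dx_q))[1:min(40, sum(!is.na(rec$dx_q)))]) {
    led <- accrue_costs(list(dx_q = rec$dx_q[i], dx_stage = rec$dx_stage[i],
                             death_q = rec$death_q[i], cause = cause_chr[i]),
                        b$costs)
    expect_equal(rec$cost[i], led$cost, tolerance = 1e-8)
    expect_equal(rec$disc_cost[i], led$disc_cost, tolerance = 1e-8)
  }
})

test_that("zero discount rate makes discounted and raw life years equal", {
  b <- default_bundle()
  b$costs$discount_rate_annual <- 0
  co <- init_cohort(5000, 0.5, b, seed = 20)
  out <- run_cohort(co, 55)$outcomes
  expect_equal(out[["disc_life_years"]], out[["life_years"]], tolerance = 1e-9)
  expect_equal(out[["disc_lyl"]], out[["lyl"]], tolerance = 1e-9)
})

test_that("compute_objectives: identities, antisymmetry of differences, flags", {
  x <- c(cases = 100, crc_deaths = 40, disc_lyl = 500, cost = 1e6)
  expect_equal(as.numeric(compute_objectives(x, x)), rep(0, 4))

  zero <- c(cases = 0, crc_deaths = 0, disc_lyl = 100, cost = 5e5)
  obj <- compute_objectives(zero, x)
  expect_equal(obj[["incidence_reduction_pct"]], 100)
  expect_equal(obj[["mortality_reduction_pct"]], 100)

  y <- c(cases = 80, crc_deaths = 30, disc_lyl = 400, cost = 9e5)
  fwd <- compute_objectives(y, x)
  # swapping arms negates the baseline - screened differences
  d_fwd <- (x - y)[c("crc_deaths", "cases", "disc_lyl", "cost")]
  d_rev <- (y - x)[c("crc_deaths", "cases", "disc_lyl", "cost")]
  expect_equal(unname(d_fwd), -unname(d_rev))

  flagged <- compute_objectives(y, c(cases = 0, crc_deaths = 30,
                                     disc_lyl = 400, cost = 9e5))
  expect_true(is.na(flagged[["incidence_reduction_pct"]]))
  expect_true("incidence_reduction_pct" %in% attr(flagged, "flagged"))
})

test_that("summary_metrics arithmetic and undefined ratios", {
  base <- c(lyl = 1000, disc_lyl = 500, cases = 100, colos_screen = 0,
            colos_surv = 0, colos_diag = 0)
  scr <- c(lyl = 950, disc_lyl = 470, cases = 90, colos_screen = 900,
           colos_surv = 80, colos_diag = 20)
  m <- summary_metrics(scr, base, n = 1000)
  expect_equal(m[["lyg_per_1000"]], 50)
  expect_equal(m[["colonoscopies_per_1000"]], 1000)
  expect_equal(m[["colonoscopies_per_lyg"]], 1000 / 50)
  expect_equal(m[["colonoscopies_per_case_prevented"]], 100)

  same <- summary_metrics(base, base, n = 1000)
  expect_true(is.na(same[["colonoscopies_per_case_prevented"]]))
})

test_that("icer arithmetic, sign and flags", {
  a <- c(disc_cost = 100, disc_life_years = 10)
  b <- c(disc_cost = 0, disc_life_years = 0)
  expect_equal(icer(a, b)$icer, 10)
  cheap <- c(disc_cost = -50, disc_life_years = 5)
  expect_lt(icer(cheap, b)$icer, 0)
  expect_identical(icer(b, b)$flag, "undefined")
  expect_identical(icer(b, a)$flag, "dominated_ordering")
})
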