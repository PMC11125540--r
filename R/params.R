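#' @useDynLib crcscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median optimize plnorm qnorm quantile rbinom runif sd
#' @importFrom utils write.csv read.csv
NULL

# colon segments, rectum last; the colonoscope enters at the rectum and the
# cecum is reached only with full intubation
SEGMENTS <- c("cecum", "ascending", "hepatic_flexure", "transverse",
              "splenic_flexure", "descending", "sigmoid", "rectum")
MAXQ <- 400L  # quarters 0..400 cover birth to age 100

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, allow_zero = TRUE) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_bad(name, " must be probabilities in [0, 1]")
  invisible(x)
}

# ------------------------------------------------------------ life table --

#' Build a quarterly life table from a Gompertz-Makeham hazard
#'
#' Produces the table of quarterly non-CRC death probabilities used for
#' competing other-cause mortality, as a parametric stand-in for a national
#' period life table. The annual hazard at age x is
#' `lambda + alpha * exp(beta * x)`, scaled by `sex_ratio_adjust` for men and
#' by its inverse for women; the quarterly death probability is
#' `1 - exp(-0.25 * h(x))`. Everyone alive at age 100 dies in the final
#' quarter (q forced to 1).
#'
#' @param makeham_level age-independent hazard component, per year
#' @param gompertz_scale scale of the exponential component, per year
#' @param gompertz_shape exponential slope, per 1/year
#' @param sex_ratio_adjust male hazards are multiplied, female hazards
#'   divided, by this factor
#' @return a `crc_life_table` data frame with columns `sex` (0 male,
#'   1 female), `age_quarter` (0-400) and `q`
#' @export
make_life_table <- function(makeham_level = 5.4e-4, gompertz_scale = 2.5e-5,
                            gompertz_shape = 0.0955, sex_ratio_adjust = 1.3) {
  if (any(c(makeham_level, gompertz_scale, gompertz_shape) < 0) ||
      sex_ratio_adjust <= 0)
    stop_bad("life-table hazard parameters must be non-negative")
  age <- (0:MAXQ) / 4
  h <- makeham_level + gompertz_scale * exp(gompertz_shape * age)
  lt <- do.call(rbind, lapply(c(0, 1), function(sx) {
    adj <- if (sx == 0) sex_ratio_adjust else 1 / sex_ratio_adjust
    q <- 1 - exp(-0.25 * h * adj)
    q[length(q)] <- 1  # nobody lives past 100
    data.frame(sex = sx, age_quarter = 0:MAXQ, q = q)
  }))
  class(lt) <- c("crc_life_table", "data.frame")
  validate_life_table(lt)
}

#' @export
validate_life_table <- function(lt) {
  if (!all(c("sex", "age_quarter", "q") %in% names(lt)))
    stop_bad("life table needs columns sex, age_quarter, q")
  check_prob(lt$q, "life table q")
  for (sx in unique(lt$sex)) {
    sub <- lt[lt$sex == sx, ]
    sub <- sub[order(sub$age_quarter), ]
    if (!identical(sub$age_quarter, 0:MAXQ))
      stop_bad("life table must cover quarters 0..400 per sex")
    if (sub$q[MAXQ + 1] != 1)
      stop_bad("life table must end with q = 1 at age 100")
    above30 <- sub$q[sub$age_quarter >= 120]
    if (any(diff(above30) < -1e-12))
      stop_bad("life table q must be non-decreasing above age 30")
  }
  invisible(lt)
}

# distribution of the other-cause death quarter implied by a life table
life_table_death_cdf <- function(lt, sex) {
  sub <- lt[lt$sex == sex, ]
  sub <- sub[order(sub$age_quarter), ]
  q <- sub$q
  surv <- cumprod(1 - q)
  pdf <- q * c(1, surv[-length(surv)])
  cdf <- cumsum(pdf)
  cdf[length(cdf)] <- 1
  cdf
}

#' Distribution of the death quarter implied by a life table
#'
#' @param lt a `crc_life_table`
#' @param sex 0 (male) or 1 (female)
#' @return numeric vector, `P(death quarter == t)` for t = 0..400; sums to 1
#' @export
life_table_death_pmf <- function(lt, sex) {
  cdf <- life_table_death_cdf(lt, sex)
  diff(c(0, cdf))
}

# ------------------------------------------------- natural-history params --

#' Natural-history parameter bundle
#'
#' Collects every disease-process rate of the adenoma-carcinoma model.
#' Age-dependent hazards are stored tabulated per quarter of age (length 401)
#' so that sensitivity scans are a vector multiplication; the packaged
#' defaults are generated from log-linear annual hazards.
#'
#' @param init_rate_m,init_rate_f per-quarter adenoma initiation probability
#'   by age quarter (length 401)
#' @param direct_rate_m,direct_rate_f per-quarter direct-path carcinoma
#'   probability from normal mucosa (length 401)
#' @param risk_sdlog log-sd of the log-normal individual adenoma risk
#'   multiplier (mean fixed at 1)
#' @param location_dist adenoma location distribution over the 8 colon
#'   segments (sums to 1)
#' @param direct_right_colon_weight multiplicative weight applied to the
#'   proximal segments (cecum..transverse) in the direct-path location draw
#' @param prog_p per-quarter adenoma stage progression probability, stages
#'   1-6 (stage 6 must be 0)
#' @param cancer_p per-quarter adenoma-to-preclinical-cancer probability by
#'   adenoma stage
#' @param pre_prog per-quarter preclinical carcinoma stage progression
#'   probability, stages I-IV (stage IV must be 0)
#' @param sympt_p per-quarter symptomatic clinical detection probability by
#'   carcinoma stage
#' @param onset_stage_dist carcinoma stage distribution at direct-path onset
#' @param surv5 5-year survival fraction by carcinoma stage at diagnosis
#' @param death_time_dist weights over quarters 1-20 after the anchor for the
#'   CRC death time (normalized internally)
#' @param adv_start first adenoma stage counted as "advanced" (default 5)
#' @param survival_anchor `"initiation"` (default) anchors the 5-year CRC
#'   death window at preclinical onset; `"diagnosis"` anchors it at diagnosis
#' @return a `crc_nh_params` object
#' @export
nh_params <- function(init_rate_m, init_rate_f, direct_rate_m, direct_rate_f,
                      risk_sdlog, location_dist, direct_right_colon_weight,
                      prog_p, cancer_p, pre_prog, sympt_p, onset_stage_dist,
                      surv5, death_time_dist, adv_start = 5L,
                      survival_anchor = c("initiation", "diagnosis")) {
  survival_anchor <- match.arg(survival_anchor)
  p <- list(
    init_rate_m = as.numeric(init_rate_m),
    init_rate_f = as.numeric(init_rate_f),
    direct_rate_m = as.numeric(direct_rate_m),
    direct_rate_f = as.numeric(direct_rate_f),
    risk_sdlog = as.numeric(risk_sdlog),
    location_dist = stats::setNames(as.numeric(location_dist), SEGMENTS),
    direct_right_colon_weight = as.numeric(direct_right_colon_weight),
    prog_p = as.numeric(prog_p), cancer_p = as.numeric(cancer_p),
    pre_prog = as.numeric(pre_prog), sympt_p = as.numeric(sympt_p),
    onset_stage_dist = as.numeric(onset_stage_dist),
    surv5 = as.numeric(surv5),
    death_time_dist = as.numeric(death_time_dist),
    adv_start = as.integer(adv_start),
    survival_anchor = survival_anchor)
  class(p) <- "crc_nh_params"
  validate_nh_params(p)
}

#' @export
validate_nh_params <- function(p) {
  for (f in c("init_rate_m", "init_rate_f", "direct_rate_m", "direct_rate_f")) {
    if (length(p[[f]]) != MAXQ + 1)
      stop_bad(f, " must have length 401 (quarters 0..400)")
    check_prob(p[[f]], f)
  }
  if (p$risk_sdlog < 0) stop_bad("risk_sdlog must be >= 0")
  if (length(p$location_dist) != 8 ||
      abs(sum(p$location_dist) - 1) > 1e-8 || any(p$location_dist < 0))
    stop_bad("location_dist must be 8 non-negative values summing to 1")
  if (p$direct_right_colon_weight <= 0)
    stop_bad("direct_right_colon_weight must be positive")
  if (length(p$prog_p) != 6 || length(p$cancer_p) != 6)
    stop_bad("prog_p and cancer_p must have length 6")
  check_prob(p$prog_p, "prog_p"); check_prob(p$cancer_p, "cancer_p")
  if (p$prog_p[6] != 0) stop_bad("stage-6 adenomas cannot progress further")
  if (length(p$pre_prog) != 4 || p$pre_prog[4] != 0)
    stop_bad("pre_prog must have length 4 with stage IV = 0")
  check_prob(p$pre_prog, "pre_prog"); check_prob(p$sympt_p, "sympt_p")
  check_prob(p$surv5, "surv5")
  if (abs(sum(p$onset_stage_dist) - 1) > 1e-8 || any(p$onset_stage_dist < 0))
    stop_bad("onset_stage_dist must sum to 1")
  if (length(p$death_time_dist) != 20 || any(p$death_time_dist < 0) ||
      sum(p$death_time_dist) <= 0)
    stop_bad("death_time_dist must be 20 non-negative weights")
  if (!p$adv_start %in% 2:6) stop_bad("adv_start must be in 2..6")
  invisible(p)
}

# flatten for the C++ engine
nh_to_cpp <- function(p) {
  w <- p$location_dist
  dw <- w
  dw[1:4] <- dw[1:4] * p$direct_right_colon_weight  # cecum..transverse
  dw <- dw / sum(dw)
  dt <- p$death_time_dist / sum(p$death_time_dist)
  list(init_rate_m = p$init_rate_m, init_rate_f = p$init_rate_f,
       direct_rate_m = p$direct_rate_m, direct_rate_f = p$direct_rate_f,
       loc_cdf = cumsum(w), direct_loc_cdf = cumsum(dw),
       onset_stage_cdf = cumsum(p$onset_stage_dist),
       death_time_cdf = cumsum(dt),
       prog_p = p$prog_p, cancer_p = p$cancer_p,
       pre_prog = p$pre_prog, sympt_p = p$sympt_p, surv5 = p$surv5,
       risk_sdlog = p$risk_sdlog, adv_start = p$adv_start,
       survival_anchor_dx = as.integer(p$survival_anchor == "diagnosis"))
}

# ---------------------------------------------------- colonoscopy params --

#' Colonoscopy performance parameters
#'
#' @param reach probabilities of passing, in order, the splenic flexure, the
#'   hepatic flexure, and of reaching the cecum given the hepatic flexure was
#'   passed; their product is the cecal intubation rate
#' @param sens_adenoma per-lesion detection sensitivity by adenoma stage,
#'   non-decreasing in stage
#' @param sens_cancer per-lesion detection sensitivity for preclinical cancer
#' @param compl_prob per-procedure probability of perforation, bleeding,
#'   serosa burn
#' @param compl_polyp_mult multiplier on complication probabilities when a
#'   polypectomy was performed
#' @param compl_fatal case-fatality of each complication type
#' @param adherence probability that an invited person attends a screening
#'   colonoscopy (surveillance and diagnostic procedures are always attended)
#' @param adherence_mode `"invitation"` draws attendance independently per
#'   invitation; `"person"` draws a single always/never attender flag
#' @return a `crc_colo_params` object
#' @export
colonoscopy_params <- function(reach = c(0.99, 0.985, 0.975),
                               sens_adenoma = c(0.75, 0.77, 0.80, 0.84, 0.90, 0.95),
                               sens_cancer = 0.95,
                               compl_prob = c(perforation = 6e-4,
                                              bleeding = 1.6e-3,
                                              serosa_burn = 3e-4),
                               compl_polyp_mult = 2,
                               compl_fatal = c(perforation = 0.05,
                                               bleeding = 0.003,
                                               serosa_burn = 0.01),
                               adherence = 1,
                               adherence_mode = c("invitation", "person")) {
  adherence_mode <- match.arg(adherence_mode)
  p <- list(reach = as.numeric(reach),
            sens_adenoma = as.numeric(sens_adenoma),
            sens_cancer = as.numeric(sens_cancer),
            compl_prob = as.numeric(compl_prob),
            compl_polyp_mult = as.numeric(compl_polyp_mult),
            compl_fatal = as.numeric(compl_fatal),
            adherence = as.numeric(adherence),
            adherence_mode = adherence_mode)
  class(p) <- "crc_colo_params"
  validate_colo_params(p)
}

#' @export
validate_colo_params <- function(p) {
  check_prob(p$reach, "reach")
  check_prob(p$sens_adenoma, "sens_adenoma")
  if (length(p$sens_adenoma) != 6) stop_bad("sens_adenoma must have length 6")
  if (any(diff(p$sens_adenoma) < -1e-12))
    stop_bad("sens_adenoma must be non-decreasing in stage")
  check_prob(p$sens_cancer, "sens_cancer")
  check_prob(p$compl_prob, "compl_prob")
  check_prob(p$compl_fatal, "compl_fatal")
  check_prob(p$adherence, "adherence")
  if (p$compl_polyp_mult < 0) stop_bad("compl_polyp_mult must be >= 0")
  invisible(p)
}

colo_to_cpp <- function(p) {
  list(reach = p$reach, sens_adenoma = p$sens_adenoma,
       sens_cancer = p$sens_cancer, compl_prob = p$compl_prob,
       compl_polyp_mult = p$compl_polyp_mult, compl_fatal = p$compl_fatal,
       adherence = p$adherence,
       adherence_per_person = as.integer(p$adherence_mode == "person"))
}

# ------------------------------------------------- surveillance guideline --

#' Post-polypectomy surveillance guideline
#'
#' Interval table keyed by colonoscopy findings: no adenoma returns the
#' person to the screening schedule; 1-2 early adenomas trigger surveillance
#' after `interval_early` years; three or more adenomas or any advanced
#' adenoma after `interval_advanced` years; detected cancer moves the person
#' to treatment. No surveillance is scheduled past `stop_age`.
#'
#' @param interval_early,interval_advanced surveillance intervals in years
#' @param stop_age age (years) after which no surveillance is scheduled
#' @export
surveillance_guideline <- function(interval_early = 5, interval_advanced = 3,
                                   stop_age = 85) {
  g <- list(interval_early = as.numeric(interval_early),
            interval_advanced = as.numeric(interval_advanced),
            stop_age = as.numeric(stop_age))
  class(g) <- "crc_guideline"
  if (g$interval_early <= 0 || g$interval_advanced <= 0)
    stop_bad("surveillance intervals must be positive")
  if (g$stop_age > 100) stop_bad("stop_age must be <= 100")
  g
}

# --------------------------------------------------------------- costs ----

#' Cost parameters (payer perspective, one currency unit)
#'
#' Treatment costs are per 3-month quarter and depend on carcinoma stage at
#' diagnosis and on the period: the first 12 months after diagnosis, the
#' follow-up interval, and the last 12 months before CRC death (which takes
#' precedence); treatment costs stop 5 years (20 quarters) after diagnosis.
#'
#' @param colonoscopy_cost,polypectomy_surcharge per-procedure costs
#' @param complication_cost per-event cost of perforation, bleeding, serosa
#'   burn
#' @param treatment_cost 4x3 matrix (stage I-IV by period
#'   initial12mo/followup/terminal12mo), per quarter
#' @param death_unrelated_terminal_cost one-time terminal cost when a
#'   diagnosed CRC patient dies of a cause other than CRC
#' @param discount_rate_annual annual discount rate (fraction)
#' @param discount_anchor_age age from which discounting starts, years
#' @export
cost_params <- function(colonoscopy_cost = 1000,
                        polypectomy_surcharge = 250,
                        complication_cost = c(perforation = 28000,
                                              bleeding = 7000,
                                              serosa_burn = 10000),
                        treatment_cost = default_treatment_cost(),
                        death_unrelated_terminal_cost = 16000,
                        discount_rate_annual = 0.03,
                        discount_anchor_age = 20) {
  p <- list(colonoscopy_cost = as.numeric(colonoscopy_cost),
            polypectomy_surcharge = as.numeric(polypectomy_surcharge),
            complication_cost = as.numeric(complication_cost),
            treatment_cost = treatment_cost,
            death_unrelated_terminal_cost =
              as.numeric(death_unrelated_terminal_cost),
            discount_rate_annual = as.numeric(discount_rate_annual),
            discount_anchor_age = as.numeric(discount_anchor_age),
            horizon_quarters = 20L)
  class(p) <- "crc_cost_params"
  validate_cost_params(p)
}

default_treatment_cost <- function() {
  # per-quarter treatment costs by stage at diagnosis and period, 2020 USD
  # magnitudes; synthetic stand-in for published US payer costs
  m <- rbind(I   = c(11500,  750, 27000),
             II  = c(16000,  900, 28000),
             III = c(21000, 1250, 30000),
             IV  = c(27500, 6250, 32000))
  colnames(m) <- c("initial12mo", "followup", "terminal12mo")
  m
}

#' @export
validate_cost_params <- function(p) {
  costs <- c(p$colonoscopy_cost, p$polypectomy_surcharge,
             p$complication_cost, as.numeric(p$treatment_cost),
             p$death_unrelated_terminal_cost)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop_bad("all costs must be finite and >= 0")
  if (!is.matrix(p$treatment_cost) || !all(dim(p$treatment_cost) == c(4, 3)))
    stop_bad("treatment_cost must be a 4x3 matrix (stage x period)")
  if (p$discount_rate_annual < 0 || p$discount_rate_annual >= 1)
    stop_bad("discount_rate_annual must be in [0, 1)")
  invisible(p)
}

cost_to_cpp <- function(p) {
  list(colonoscopy_cost = p$colonoscopy_cost,
       polypectomy_surcharge = p$polypectomy_surcharge,
       complication_cost = p$complication_cost,
       treatment_cost = unname(p$treatment_cost),
       death_unrelated_terminal_cost = p$death_unrelated_terminal_cost)
}

# -------------------------------------------------------------- bundles ---

#' Packaged parameter bundles
#'
#' Returns a complete, internally consistent set of natural-history,
#' colonoscopy, surveillance, cost and life-table parameters. Deterministic
#' (no random numbers). Available scenarios:
#' \describe{
#'   \item{default_us}{calibrated defaults whose no-screening lifetime CRC
#'     risk, adenoma prevalence and age-incidence shape are in the range of
#'     pre-screening US magnitudes}
#'   \item{null_disease}{all lesion initiation rates zero; nobody ever
#'     develops CRC (useful as a degenerate control)}
#' }
#'
#' @param scenario_name bundle label
#' @return a `crc_bundle` list with elements `nh`, `colo`, `guideline`,
#'   `costs`, `life_table`, `scenario`
#' @export
make_default_params <- function(scenario_name = "default_us") {
  known <- c("default_us", "null_disease")
  if (!scenario_name %in% known)
    stop_bad("unknown scenario '", scenario_name, "'; available: ",
             paste(known, collapse = ", "))
  age <- (0:MAXQ) / 4
  # Annual adenoma initiation hazard: log-linear in age, plateau above 66,
  # with a sub-40 onset ramp reproducing the low adenoma/carcinoma incidence
  # at ages 40-50 characteristic of this model class. Calibrated (see the
  # methods vignette) so that no-screening lifetime CRC risk ~ 6%, adenoma
  # prevalence ~ 30% at 60, and the age-incidence curve matches
  # pre-screening US magnitudes.
  ramp <- pmin(pmax((age - 22) / 15, 0), 1)^1.25
  base_init <- 0.0060 * exp(0.055 * (pmin(age, 66) - 40)) * ramp
  init_m <- 1 - exp(-0.25 * base_init * 1.25)
  init_f <- 1 - exp(-0.25 * base_init / 1.25)
  # direct carcinoma path (hard-to-prevent cancers): rare, age-increasing;
  # ~ 25% of symptomatic cases
  base_dir <- 2.9e-5 * exp(0.062 * pmin(pmax(age - 20, 0), 55)) * ramp
  dir_m <- 1 - exp(-0.25 * base_dir * 1.15)
  dir_f <- 1 - exp(-0.25 * base_dir / 1.15)
  # CRC death times concentrate in the first 2-3 years (median ~ 2 y)
  dt <- stats::plnorm(1:20 / 4, meanlog = log(2.0), sdlog = 0.55) -
    stats::plnorm(0:19 / 4, meanlog = log(2.0), sdlog = 0.55)
  nh <- nh_params(
    init_rate_m = init_m, init_rate_f = init_f,
    direct_rate_m = dir_m, direct_rate_f = dir_f,
    risk_sdlog = 0.65,
    location_dist = c(0.13, 0.13, 0.04, 0.11, 0.04, 0.11, 0.27, 0.17),
    direct_right_colon_weight = 2.0,
    prog_p = c(0.080, 0.080, 0.080, 0.042, 0.052, 0),
    cancer_p = c(1e-5, 2e-5, 5e-5, 1.4e-4, 8.5e-4, 3.4e-3),
    pre_prog = c(0.16, 0.17, 0.18, 0),
    sympt_p = c(0.02, 0.06, 0.15, 0.32),
    onset_stage_dist = c(0.75, 0.18, 0.06, 0.01),
    surv5 = c(0.92, 0.80, 0.60, 0.08),
    death_time_dist = dt)
  if (scenario_name == "null_disease") {
    nh$init_rate_m[] <- 0; nh$init_rate_f[] <- 0
    nh$direct_rate_m[] <- 0; nh$direct_rate_f[] <- 0
  }
  b <- list(nh = nh, colo = colonoscopy_params(),
            guideline = surveillance_guideline(), costs = cost_params(),
            life_table = make_life_table(), scenario = scenario_name)
  class(b) <- "crc_bundle"
  b
}

#' @export
validate_bundle <- function(b) {
  validate_nh_params(b$nh)
  validate_colo_params(b$colo)
  validate_cost_params(b$costs)
  validate_life_table(b$life_table)
  invisible(b)
}

# ------------------------------------------------------- serialization ----

#' Write / read a parameter bundle as JSON
#'
#' Numbers are serialized at full precision so bundles round-trip exactly.
#'
#' @param bundle a `crc_bundle`
#' @param path file path
#' @export
write_bundle <- function(bundle, path) {
  b <- unclass(bundle)
  b$nh <- unclass(b$nh)
  b$colo <- unclass(b$colo)
  b$guideline <- unclass(b$guideline)
  b$costs <- unclass(b$costs)
  b$costs$treatment_cost <- list(
    values = as.numeric(b$costs$treatment_cost),
    dim = dim(bundle$costs$treatment_cost),
    dimnames = dimnames(bundle$costs$treatment_cost))
  b$life_table <- as.data.frame(unclass(b$life_table))
  # 17 significant digits guarantee a bit-exact double round trip
  jsonlite::write_json(b, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tc <- matrix(as.numeric(j$costs$treatment_cost$values), 4, 3)
  dimnames(tc) <- j$costs$treatment_cost$dimnames
  nh <- do.call(nh_params, c(
    j$nh[c("init_rate_m", "init_rate_f", "direct_rate_m", "direct_rate_f",
           "risk_sdlog", "location_dist", "direct_right_colon_weight",
           "prog_p", "cancer_p", "pre_prog", "sympt_p", "onset_stage_dist",
           "surv5", "death_time_dist", "adv_start")],
    list(survival_anchor = j$nh$survival_anchor)))
  colo <- colonoscopy_params(
    reach = j$colo$reach, sens_adenoma = j$colo$sens_adenoma,
    sens_cancer = j$colo$sens_cancer, compl_prob = j$colo$compl_prob,
    compl_polyp_mult = j$colo$compl_polyp_mult,
    compl_fatal = j$colo$compl_fatal, adherence = j$colo$adherence,
    adherence_mode = j$colo$adherence_mode)
  costs <- cost_params(
    colonoscopy_cost = j$costs$colonoscopy_cost,
    polypectomy_surcharge = j$costs$polypectomy_surcharge,
    complication_cost = j$costs$complication_cost,
    treatment_cost = tc,
    death_unrelated_terminal_cost = j$costs$death_unrelated_terminal_cost,
    discount_rate_annual = j$costs$discount_rate_annual,
    discount_anchor_age = j$costs$discount_anchor_age)
  lt <- j$life_table
  class(lt) <- c("crc_life_table", "data.frame")
  b <- list(nh = nh, colo = colo,
            guideline = surveillance_guideline(
              j$guideline$interval_early, j$guideline$interval_advanced,
              j$guideline$stop_age),
            costs = costs, life_table = validate_life_table(lt),
            scenario = j$scenario)
  class(b) <- "crc_bundle"
  b
}

#' Write / read a life table or benchmark table as CSV
#' @param x table to write
#' @param path file path
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param class_ S3 class to restore on read
#' @export
read_table_csv <- function(path, class_ = NULL) {
  x <- utils::read.csv(path)
  if (!is.null(class_)) class(x) <- c(class_, "data.frame")
  x
}
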