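# Pure-R quarterly stepping engine.
#
# This is a direct, person-by-person implementation of the disease and
# screening dynamics in 3-month steps. It is far too slow for schedule
# searches but serves as an independent implementation of the same model:
# the compiled overlay engine is validated against it (and against a
# closed-form Markov oracle) on small cohorts. Randomness comes from R's
# global RNG (Mersenne-Twister under set.seed()).

#' Create one simulated person at age 0
#'
#' @param id person id
#' @param sex 0 male, 1 female
#' @param risk_multiplier individual adenoma risk multiplier
#' @return a `crc_person` list
#' @export
new_person <- function(id, sex, risk_multiplier = 1) {
  structure(list(
    id = id, sex = as.integer(sex), risk = risk_multiplier,
    age_q = 0L, alive = TRUE, cause_death = NA_character_,
    death_q = NA_integer_,
    ad_stage = integer(0), ad_loc = integer(0), ad_init = integer(0),
    ad_removed = logical(0), ad_transformed = logical(0),
    ca_stage = integer(0), ca_status = character(0), ca_origin = character(0),
    ca_loc = integer(0), ca_onset = integer(0), ca_dx = integer(0),
    ca_death = integer(0),
    diagnosed = FALSE, dx_q = NA_integer_, dx_stage = NA_integer_,
    n_colos_screen = 0L, n_colos_surv = 0L, n_colos_diag = 0L,
    n_polyp = 0L, next_colonoscopy_due = NA_integer_),
    class = "crc_person")
}

# lookup tables the stepping engine needs, extracted once
prepare_stepping <- function(bundle) {
  lt <- bundle$life_table
  q <- rbind(lt$q[lt$sex == 0][order(lt$age_quarter[lt$sex == 0])],
             lt$q[lt$sex == 1][order(lt$age_quarter[lt$sex == 1])])
  nh <- bundle$nh
  dw <- nh$location_dist
  dw[1:4] <- dw[1:4] * nh$direct_right_colon_weight
  list(q = q, nh = nh,
       init = rbind(nh$init_rate_m, nh$init_rate_f),
       direct = rbind(nh$direct_rate_m, nh$direct_rate_f),
       loc_p = nh$location_dist, direct_loc_p = dw / sum(dw),
       dtd = nh$death_time_dist / sum(nh$death_time_dist))
}

#' Schedule (or not) a CRC death for a newly diagnosed cancer
#'
#' With probability `1 - surv5[stage at diagnosis]` a CRC death quarter is
#' drawn from the death-time distribution over the 20 quarters after the
#' anchor (cancer initiation by default), clamped to not precede diagnosis.
#'
#' @param onset_q,dx_q,stage cancer onset and diagnosis quarters, stage at
#'   diagnosis (1-4)
#' @param nh a `crc_nh_params`
#' @return death quarter, or `NA` if the person survives this cancer
#' @export
schedule_crc_death <- function(onset_q, dx_q, stage, nh) {
  if (runif(1) >= 1 - nh$surv5[stage]) return(NA_integer_)
  w <- nh$death_time_dist / sum(nh$death_time_dist)
  off <- sample.int(20, 1, prob = w)
  anchor <- if (nh$survival_anchor == "diagnosis") dx_q else onset_q
  dq <- max(anchor + off, dx_q)
  # the death window closes 20 quarters after the anchor; a diagnosis made
  # after that point can no longer kill
  if (dq > anchor + 20) NA_integer_ else dq
}

#' Advance one person by one quarter
#'
#' Applies, in fixed order: other-cause death; adenoma initiation (hazard
#' times the personal risk multiplier) and direct-path cancer initiation;
#' per-adenoma malignant transformation and stage progression; preclinical
#' cancer symptomatic detection and stage progression; the scheduled CRC
#' death check. Errors if the person is already dead.
#'
#' @param person a `crc_person`
#' @param ctx stepping context from the internal preparation of a bundle
#'   (or a `crc_bundle`, prepared on the fly)
#' @return the updated person
#' @export
step_quarter <- function(person, ctx) {
  if (!person$alive) stop_bad("step_quarter called on a dead person")
  if (inherits(ctx, "crc_bundle")) ctx <- prepare_stepping(ctx)
  nh <- ctx$nh
  t <- person$age_q
  sx <- person$sex + 1L
  # 1. other-cause death
  if (runif(1) < ctx$q[sx, t + 1]) {
    person$alive <- FALSE; person$cause_death <- "other"
    person$death_q <- t
    return(person)
  }
  # 2. new lesions
  if (runif(1) < min(1, ctx$init[sx, t + 1] * person$risk)) {
    person$ad_stage <- c(person$ad_stage, 1L)
    person$ad_loc <- c(person$ad_loc,
                       sample.int(8, 1, prob = ctx$loc_p) - 1L)
    person$ad_init <- c(person$ad_init, t)
    person$ad_removed <- c(person$ad_removed, FALSE)
    person$ad_transformed <- c(person$ad_transformed, FALSE)
  }
  if (runif(1) < ctx$direct[sx, t + 1]) {
    st <- sample.int(4, 1, prob = nh$onset_stage_dist)
    person <- add_cancer(person, st, "direct_path",
                         sample.int(8, 1, prob = ctx$direct_loc_p) - 1L, t)
  }
  # 3. adenoma transformation and progression
  for (a in seq_along(person$ad_stage)) {
    if (person$ad_removed[a] || person$ad_transformed[a]) next
    s <- person$ad_stage[a]
    if (runif(1) < nh$cancer_p[s]) {
      person$ad_transformed[a] <- TRUE
      person <- add_cancer(person, 1L, "adenoma_pathway", person$ad_loc[a], t)
    } else if (s < 6 && runif(1) < nh$prog_p[s]) {
      person$ad_stage[a] <- s + 1L
    }
  }
  # 4. preclinical cancer detection and progression
  for (cc in seq_along(person$ca_stage)) {
    if (person$ca_status[cc] != "preclinical") next
    s <- person$ca_stage[cc]
    if (runif(1) < nh$sympt_p[s]) {
      person$ca_status[cc] <- "symptomatic"
      person$ca_dx[cc] <- t
      person$n_colos_diag <- person$n_colos_diag + 1L
      dq <- schedule_crc_death(person$ca_onset[cc], t, s, nh)
      person$ca_death[cc] <- if (is.na(dq)) NA_integer_ else as.integer(dq)
      if (!person$diagnosed) {
        person$diagnosed <- TRUE; person$dx_q <- t; person$dx_stage <- s
      }
    } else if (s < 4 && runif(1) < nh$pre_prog[s]) {
      person$ca_stage[cc] <- s + 1L
    }
  }
  # 5. scheduled CRC death
  dth <- person$ca_death[!is.na(person$ca_death)]
  if (length(dth) && min(dth) <= t) {
    person$alive <- FALSE; person$cause_death <- "crc"
    person$death_q <- t
    return(person)
  }
  person$age_q <- t + 1L
  person
}

add_cancer <- function(person, stage, origin, loc, t) {
  person$ca_stage <- c(person$ca_stage, as.integer(stage))
  person$ca_status <- c(person$ca_status, "preclinical")
  person$ca_origin <- c(person$ca_origin, origin)
  person$ca_loc <- c(person$ca_loc, as.integer(loc))
  person$ca_onset <- c(person$ca_onset, as.integer(t))
  person$ca_dx <- c(person$ca_dx, NA_integer_)
  person$ca_death <- c(person$ca_death, NA_integer_)
  person
}

#' Perform one colonoscopy on a person (stepping engine)
#'
#' Draws the reached extent (sequential boundary passages from the rectum),
#' detects each lesion in reached segments with its stage-specific
#' sensitivity, removes detected adenomas, diagnoses detected preclinical
#' cancers, and draws complications (possibly fatal).
#'
#' @param person a living `crc_person`
#' @param colo a `crc_colo_params`
#' @param nh a `crc_nh_params` (for CRC death scheduling on detection)
#' @param type `"screening"`, `"surveillance"` or `"diagnostic"`
#' @return list with the updated `person` and the colonoscopy `result`
#' @export
perform_colonoscopy <- function(person, colo, nh,
                                type = c("screening", "surveillance",
                                         "diagnostic")) {
  type <- match.arg(type)
  if (!person$alive) stop_bad("colonoscopy on a dead person")
  level <- 0L
  for (b in 1:3) {
    if (runif(1) < colo$reach[b]) level <- level + 1L else break
  }
  visible <- function(seg) {
    if (seg >= 5) TRUE else if (seg >= 3) level >= 1
    else if (seg >= 1) level >= 2 else level >= 3
  }
  n_early <- 0L; n_adv <- 0L; cancer_found <- FALSE
  for (a in seq_along(person$ad_stage)) {
    if (person$ad_removed[a] || person$ad_transformed[a]) next
    if (!visible(person$ad_loc[a])) next
    s <- person$ad_stage[a]
    if (runif(1) < colo$sens_adenoma[s]) {
      person$ad_removed[a] <- TRUE
      person$n_polyp <- person$n_polyp + 1L
      if (s >= nh$adv_start) n_adv <- n_adv + 1L else n_early <- n_early + 1L
    }
  }
  for (cc in seq_along(person$ca_stage)) {
    if (cancer_found || person$ca_status[cc] != "preclinical") next
    if (!visible(person$ca_loc[cc])) next
    if (runif(1) < colo$sens_cancer) {
      cancer_found <- TRUE
      person$ca_status[cc] <- "screen_detected"
      s <- person$ca_stage[cc]
      person$ca_dx[cc] <- person$age_q
      dq <- schedule_crc_death(person$ca_onset[cc], person$age_q, s, nh)
      person$ca_death[cc] <- if (is.na(dq)) NA_integer_ else as.integer(dq)
      if (!person$diagnosed) {
        person$diagnosed <- TRUE
        person$dx_q <- person$age_q
        person$dx_stage <- s
      }
    }
  }
  slot <- c(screening = "n_colos_screen", surveillance = "n_colos_surv",
            diagnostic = "n_colos_diag")[[type]]
  person[[slot]] <- person[[slot]] + 1L
  mult <- if (n_early + n_adv > 0) colo$compl_polyp_mult else 1
  for (k in 1:3) {
    if (runif(1) < min(1, colo$compl_prob[k] * mult)) {
      if (runif(1) < colo$compl_fatal[k]) {
        person$alive <- FALSE
        person$cause_death <- "complication"
        person$death_q <- person$age_q
      }
    }
  }
  result <- list(findings_category = findings_category(n_early, n_adv,
                                                       cancer_found),
                 n_early = n_early, n_adv = n_adv,
                 cancer_found = cancer_found, age = person$age_q / 4)
  list(person = person, result = result)
}

#' Run a small cohort with the stepping engine
#'
#' Reference implementation used for validating the compiled engine: loops
#' persons and quarters, applying screening invitations (with per-invitation
#' adherence), guideline surveillance, symptomatic diagnosis and all death
#' causes. Use small `n`; this is O(n * 400) R-level steps.
#'
#' @param n cohort size
#' @param bundle a `crc_bundle`
#' @param schedule integer screening ages or NULL
#' @param seed seed for R's RNG
#' @param sex_fraction_male fraction male
#' @return data frame, one row per person
#' @export
reference_run_cohort <- function(n, bundle, schedule = NULL, seed = 1,
                                 sex_fraction_male = 0.5) {
  set.seed(seed)
  ctx <- prepare_stepping(bundle)
  if (!is.null(schedule) && length(schedule))
    schedule <- validate_schedule(schedule)$ages
  sched_q <- if (length(schedule)) as.integer(schedule * 4) else integer(0)
  colo <- bundle$colo
  g <- bundle$guideline
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sx <- if (runif(1) < sex_fraction_male) 0L else 1L
    rm_ <- if (ctx$nh$risk_sdlog > 0)
      exp(rnorm(1, -0.5 * ctx$nh$risk_sdlog^2, ctx$nh$risk_sdlog)) else 1
    p <- new_person(i, sx, rm_)
    surveillance_due <- NA_integer_
    si <- 1L
    while (p$alive && p$age_q <= MAXQ) {
      t <- p$age_q
      # colonoscopy events at the start of the quarter
      if (!p$diagnosed) {
        if (!is.na(surveillance_due) && t == surveillance_due) {
          surveillance_due <- NA_integer_
          pc <- perform_colonoscopy(p, colo, ctx$nh, "surveillance")
          p <- pc$person
          if (p$alive && !pc$result$cancer_found) {
            iv <- next_surveillance(pc$result, g)
            if (!is.null(iv)) surveillance_due <- t + as.integer(iv * 4)
          }
        } else if (si <= length(sched_q) && t == sched_q[si] &&
                   is.na(surveillance_due)) {
          si <- si + 1L
          if (runif(1) < colo$adherence) {
            pc <- perform_colonoscopy(p, colo, ctx$nh, "screening")
            p <- pc$person
            if (p$alive && !pc$result$cancer_found) {
              iv <- next_surveillance(pc$result, g)
              if (!is.null(iv)) surveillance_due <- t + as.integer(iv * 4)
            }
          }
        } else if (!is.na(surveillance_due) && si <= length(sched_q) &&
                   t == sched_q[si]) {
          si <- si + 1L  # surveillance overrides this invitation
        }
      }
      if (!p$alive) break
      p <- step_quarter(p, ctx)
    }
    if (p$alive) { # guard: q = 1 at quarter 400 should have killed everyone
      p$alive <- FALSE; p$cause_death <- "other"; p$death_q <- MAXQ
    }
    out[[i]] <- data.frame(
      id = i, sex = sx, risk_multiplier = rm_, death_q = p$death_q,
      cause = p$cause_death, dx_q = p$dx_q, dx_stage = p$dx_stage,
      n_adenomas = length(p$ad_stage), n_cancers = length(p$ca_stage),
      colos_screening = p$n_colos_screen, colos_surveillance = p$n_colos_surv,
      colos_diagnostic = p$n_colos_diag, polypectomies = p$n_polyp)
  }
  do.call(rbind, out)
}
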