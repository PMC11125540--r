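---
title: "crcscreen: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crcscreen: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`crcscreen` is an individual-level microsimulation of the colorectal
adenoma–carcinoma sequence with a colonoscopy screening intervention layer.
Each simulated person is followed in 3-month steps from birth to a maximum
age of 100. The disease process has:

* **Adenoma initiation.** A per-quarter hazard that depends on sex and age,
  multiplied by a person-specific log-normal risk factor with mean 1
  (`risk_sdlog`, default 0.65). Each adenoma receives a fixed colon segment
  (8 segments, cecum to rectum) drawn from `location_dist`.
* **Six adenoma stages.** Stages 1–4 are "early", 5–6 "advanced" (the
  boundary is the `adv_start` constant). Per quarter an adenoma in stage
  *s* transforms to preclinical carcinoma with probability `cancer_p[s]`,
  otherwise advances one stage with probability `prog_p[s]`. Stage 6 can
  only transform.
* **A direct carcinoma path.** Cancer can also arise from apparently normal
  mucosa at a small, age-increasing per-quarter rate with a 2-fold weight
  on the proximal colon. This represents hard-to-prevent cancers (serrated
  pathway, missed or very fast lesions) and sets the ceiling on what
  screening can achieve.
* **Four preclinical carcinoma stages.** Per quarter a preclinical cancer
  becomes symptomatic (clinically diagnosed) with stage-specific
  probability `sympt_p[s]`, otherwise progresses with `pre_prog[s]`.
* **Death.** Other-cause mortality follows a quarterly life table
  (Gompertz–Makeham stand-in for the 2008 US period life table; the final
  quarter forces q = 1 so nobody outlives 100). CRC death is restricted to
  the 20 quarters after cancer initiation: at diagnosis, the person dies
  with probability `1 - surv5[stage at diagnosis]` at a time drawn from
  `death_time_dist`, clamped to not precede diagnosis; if the drawn time
  falls outside the 5-year window (that is, diagnosis came too late for the
  scheduled death), the person survives the cancer. A config switch
  (`survival_anchor = "diagnosis"`) anchors the window at diagnosis
  instead; the default is initiation-anchored. Colonoscopy complications
  can also kill.

**Screening layer.** Colonoscopies happen at scheduled integer ages
(20–90, at most four, at least 5 years apart), at guideline surveillance
appointments, or for symptomatic workup. Reach is three sequential
boundary-passage Bernoulli draws (splenic flexure, hepatic flexure, cecum);
their product is the cecal intubation rate (defaults give ≈ 0.95). Each
lesion in a reached segment is independently detected with stage-specific
sensitivity; detected adenomas are removed (their downstream cancers never
happen), detected preclinical cancers are staged and diagnosed. Surveillance
follows a findings table (1–2 early adenomas → 5 y; ≥3 or any advanced → 3
y; none → back to screening; stop age 85) and overrides screening
invitations while active. Adherence applies per screening invitation
(Bernoulli, default 100%); surveillance and diagnostic colonoscopies are
always attended. A per-person always/never mode is available
(`adherence_mode = "person"`).

**Outcomes.** The four objectives compare a screened arm with the paired
no-screening arm: percent reductions of CRC deaths, of diagnosed cases, of
discounted life-years-lost and of total cost. Life-years-lost is the gap
between the person's other-cause death time and their actual death time, so
it captures CRC deaths and fatal complications, person-paired across arms.
Discounting is 3%/year anchored at age 20 and clamped to factor 1 before
the anchor (flows before age 20 are not inflated). Treatment costs accrue
quarterly with one category per quarter — last-12-months-before-CRC-death
takes precedence over first-12-months-after-diagnosis, then follow-up —
and stop 5 years after diagnosis.

# Engine design: precompute + overlay

Screening in this model can only remove lesions or diagnose them earlier;
lesion initiation and progression are unaffected by the intervention. The
compiled engine therefore simulates each person's *potential* natural
history once (other-cause death quarter, every potential adenoma with its
staged trajectory and transformation time, every potential cancer with its
staged course, symptomatic-detection time and pre-drawn fate uniforms), and
evaluates any schedule as a cheap overlay on this fixed history. One
evaluation of a 200,000-person arm takes ~20 ms, which is what makes
exhaustive landscapes (71 single ages, 2211 pairs) and metaheuristic
searches affordable on one CPU.

Common random numbers operate at two levels:

* **Across arms:** both arms of a comparison share the same histories, so
  objective differences are person-paired.
* **Across schedules:** screening draws are keyed by *what they decide*
  (person, lesion, exam index, complication type) rather than by position
  in a stream, so schedules differing by one age reuse identical uniforms
  for corresponding decisions. This makes the optimization landscapes
  smooth enough that the argmax of a flat objective is stable at desk
  scale.

Natural histories use a 64-bit Mersenne Twister; the screening overlay uses
keyed splitmix64 draws (recorded in the run manifest). The fate uniform of
each cancer is drawn once, so an earlier (screen-detected) stage — with its
higher survival — can only remove a death, never add one (monotone
coupling).

A pure-R quarterly stepping engine (`new_person()`, `step_quarter()`,
`perform_colonoscopy()`, `reference_run_cohort()`) implements the same
rules person-by-person. It is validated against the compiled engine
distributionally and against an exact Markov-chain oracle on
constant-hazard configurations; it is the reference for what the fast
engine must do, not a production path.

# The packaged calibration ("default_us")

The original model's parameter values are not printed in the sources this
package is built from, so the defaults are parametric stand-ins calibrated
**only to epidemiological magnitudes**, not to any screening outcome:

* 2008-US-like life table (life expectancy ≈ 75.6 male / 81.6 female);
* no-screening lifetime CRC risk ≈ 6%, CRC mortality/incidence ≈ 0.4
  (SEER 1988–2002-era stage survival: 0.92/0.80/0.60/0.08);
* adenoma prevalence ≈ 20% at 50, 30% at 60, 43% at 70;
* pre-screening US-like age–incidence curve (≈ 70 per 100k/yr at 50–54
  rising to ≈ 450 at 80–84), including the deliberately low incidence at
  ages 40–50 that this model class is known to produce;
* median adenoma dwell time ≈ 25 years (initiation to preclinical cancer
  among transforming adenomas), median preclinical sojourn ≈ 2.8 years;
* ≈ 25% of symptomatic cancers from the direct path.

Under this bundle the optimization landscape puts the single-colonoscopy
optima at ≈ 54 (discounted life-years-lost), ≈ 63–64 (incidence) and
≈ 64–65 (mortality); the two-colonoscopy discounted-LYL optimum at ≈
(47–49, 63–65). The landscapes are flat near their optima (the 95% regions
span roughly a decade), so at the acceptance scale (n = 2×10⁵, 3
replicates) the reported argmax can move by 1–2 years between seeds. A
known residual of the calibration is a 1–3 year late bias of the
incidence- and mortality-optimal ages relative to the published model;
sharpening this would require the original transition parameters.

**What a green test establishes.** The synthetic world reproduces the
structure of the published results — the ordering LYG-optimum <
incidence-optimum < mortality-optimum, the earlier start with more
colonoscopies, the directional sensitivity findings, the qualitative
cost-effectiveness ladder — at reduced population size. It does not
reproduce registry-calibrated absolute values (e.g. ICERs in dollars),
which depend on external cost tables and the original calibration.

# Numerical and design choices

* **Event order within a quarter:** colonoscopy events at the start of the
  quarter (screening before symptomatic workup on ties), then other-cause
  death, lesion initiation, adenoma progression/transformation, preclinical
  progression/detection, scheduled CRC death. Other-cause death occurs at
  the end of its quarter; life years = (death quarter + 1)/4.
* **Stage at symptomatic diagnosis** equals the current preclinical stage
  (no resampling from a stage-at-diagnosis table).
* **Tie-breaks:** equal objective values resolve to the lexicographically
  earliest schedule. The "balanced solution" of a Pareto archive is the
  member minimizing the maximum relative shortfall across the four
  objectives — a documented choice, since no published rule exists.
* **Schedule evaluation noise:** each schedule is evaluated on R paired
  replicates (default 3 at desk scale; 10 mirrors the published protocol)
  and ranked by the median objective.
* **Metaheuristic:** an archive-based stand-in for a mixed-integer
  ant-colony solver — non-dominated archive, proposals by integer Gaussian
  jitter of archive members (kernel width annealed 8 → 1 year) plus 25%
  uniform restarts, and a repair operator (sort, clamp to 20–90, push
  apart to 5-year gaps) that provably returns valid schedules. Acceptance
  is via brute-force equivalence at small k, not via matching any
  proprietary solver's trajectory.
* **Costs:** the packaged cost table is a synthetic stand-in at 2020-USD
  magnitudes (colonoscopy 1000; stage- and period-specific quarterly
  treatment costs; one-time terminal cost when a diagnosed patient dies of
  another cause). Only one treatment category accrues per quarter;
  procedure and complication costs accrue at their event quarter.
* **Calibration routine:** `calibrate_adenoma_scale()` fits a single
  multiplier on the adenoma initiation rates to a benchmark prevalence
  curve by bracketed scalar search on the log scale under fixed seeds
  (common random numbers make the noisy objective effectively smooth).
  Full multi-parameter calibration is intentionally out of scope.
* **Serialization:** bundles round-trip through JSON bit-exactly (17
  significant digits); life tables and benchmark tables also read/write as
  CSV.

# Locating flat optima

The objective landscapes are flat near their maxima: the 95%-of-maximum
region of the single-colonoscopy curves spans roughly a decade, and the
argmax of a noisy flat curve jitters by 1–2 years between seeds even at
n = 2×10⁵ with three replicates. `optimum_region()` therefore reports,
besides the argmax, the near-optimal region, its centroid, and (for
single-age landscapes) the vertex of a local parabola fitted in a ±5-year
window around the argmax. The vertex is the estimator used by the
directional sensitivity checks, with a pre-stated one-sided Monte-Carlo
tolerance of one year.

# Risk stratification is nearly scale-invariant

The personalized-screening module stratifies the population with mean-one
multiplicative risk factors (`stratification_multipliers()` solves
`f·m_high + (1−f)·m_low = 1`, `m_high = rr·m_low`). Because all four
objectives are *percent* reductions, a uniform multiplicative change of
lesion initiation leaves them nearly invariant, and the optimal ages of the
high- and low-risk groups differ by only ~0–1 year in this package — the
residual comes from multiple-adenoma saturation, surveillance chains and
CRC-death feedback. Published models that report multi-year personalization
shifts construct the risk groups differently (e.g. by selecting individuals
on their eventual cancer outcome); with calibrated mean-one multipliers the
direction, not the magnitude, is the testable claim.

# Known limitations

* No serrated-pathway states, adenoma regression, QALYs, or
  modality alternatives (FIT, sigmoidoscopy); costs are payer-perspective
  with a single discount rate.
* Costs accrue for the first diagnosed cancer only; later primaries in the
  same person are not separately costed (they are rare and do not affect
  the objectives materially).
* The stepping engine omits complications at symptomatic diagnostic
  colonoscopies (the compiled engine includes them); the difference is
  ~0.2% of procedures and invisible at test tolerances.
* At very low adherence, surveillance dynamics after a skipped first
  invitation differ from models that re-invite; we treat each invitation
  independently (default) or per-person (config).
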