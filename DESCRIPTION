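Package: crcscreen
Title: Colorectal Cancer Natural-History Microsimulation and Colonoscopy
    Schedule Optimization
Version: 0.1.0
Authors@R:
    person("crcscreen", "developers", email = "crcscreen@example.org",
           role = c("aut", "cre"))
Description: Individual-level microsimulation of the colorectal
    adenoma-carcinoma sequence (six adenoma stages, four preclinical
    carcinoma stages, a direct carcinoma path, competing other-cause
    mortality) in 3-month time steps from birth to age 100, with a
    colonoscopy screening intervention model (anatomical reach, per-lesion
    detection, polypectomy, complications, guideline-driven surveillance).
    Computes incidence, mortality, discounted life-years-lost and cost
    reductions of integer-age screening schedules against a paired
    no-screening arm under common random numbers, searches for optimal and
    Pareto-optimal schedules of one to four colonoscopies (exhaustive
    enumeration, Kung's non-dominated filter, and an archive-based
    ant-colony metaheuristic), and runs one-way sensitivity, bound-scenario
    and risk-stratified screening experiments with cost-effectiveness
    (ICER) summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
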