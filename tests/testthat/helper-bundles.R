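# Shared fixtures, built in code. Small cohorts keep the unit suite fast;
# the acceptance suite uses the spec's stated scales.

default_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- make_default_params()
    b
  }
})

null_bundle <- function() make_default_params("null_disease")

# bundle with a single constant-hazard adenoma process and everything else
# switched off; useful for Poisson / Markov oracle checks
constant_adenoma_bundle <- function(h_quarter = 0.002,
                                    prog = rep(0, 6), cancer = rep(0, 6),
                                    sdlog = 0) {
  b <- make_default_params()
  b$nh$init_rate_m[] <- h_quarter
  b$nh$init_rate_f[] <- h_quarter
  b$nh$direct_rate_m[] <- 0
  b$nh$direct_rate_f[] <- 0
  b$nh$prog_p <- prog
  b$nh$cancer_p <- cancer
  b$nh$risk_sdlog <- sdlog
  b
}

# immortal-until-100 life table (q = 0 except the forced final quarter)
no_death_life_table <- function() make_life_table(0, 0, 0, 1)

with_life_table <- function(b, lt) { b$life_table <- lt; b }

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.4g within %.3g of %.4g", x, tol, target))
}

matpow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

# O(n^2) pairwise non-domination oracle (maximization)
pairwise_front <- function(m) {
  n <- nrow(m)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}
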