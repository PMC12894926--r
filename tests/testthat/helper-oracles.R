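# Independent simulation oracles: direct exponential survival generators
# that never go through simulate_cohort(), used to check the estimators.

# binary (or continuous) exposure, constant hazards, fixed censoring
sim_exp_surv <- function(n, loghr, rate0 = 0.01, cens = 10,
                         x = rbinom(n, 1, 0.5)) {
  rate <- rate0 * exp(loghr * x)
  t <- rexp(n, rate)
  data.frame(x = x,
             time_years = pmin(t, cens),
             aaa_event = as.integer(t <= cens),
             death_event = 0L)
}

# four-cell hazard structure for additive-interaction checks
sim_cell_surv <- function(n, hr10, hr01, hr11, rate0 = 0.005, cens = 12) {
  e <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 1, 0.5)
  hr <- ifelse(e == 1 & g == 1, hr11,
               ifelse(e == 1, hr10, ifelse(g == 1, hr01, 1)))
  t <- rexp(n, rate0 * hr)
  data.frame(exposed = e, highrisk = g,
             time_years = pmin(t, cens),
             aaa_event = as.integer(t <= cens),
             death_event = 0L)
}

# time-varying effect (log hazard ratio proportional to log t) for
# proportional-hazards power checks; inverse-transform sampling
sim_tv_surv <- function(n, beta = 1, rate0 = 0.02, cens = 10) {
  x <- rbinom(n, 1, 0.5)
  e <- rexp(n)
  t <- ifelse(x == 1,
              ((beta + 1) * e / rate0)^(1 / (beta + 1)),
              e / rate0)
  data.frame(x = x, time_years = pmin(t, cens),
             aaa_event = as.integer(t <= cens), death_event = 0L)
}

# shared large synthetic cohort for recovery checks (built once per run)
.cohort_cache <- new.env(parent = emptyenv())
big_cohort <- function(n = 50000, seed = 20260921) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(
      simulation_config(n_participants = n, seed = seed))
  }
  .cohort_cache[[key]]
}

small_cohort <- function(n = 2000, seed = 11, ...) {
  simulate_cohort(simulation_config(n_participants = n, seed = seed, ...))
}
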