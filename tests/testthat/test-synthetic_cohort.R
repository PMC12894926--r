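test_that("config validation rejects malformed inputs", {
  expect_error(simulation_config(n_participants = 1),
               class = "bioagerisk_size_error")
  expect_error(simulation_config(allele_freqs = c(rep(0.3, 30), 1.2)),
               class = "bioagerisk_config_error")
  expect_error(simulation_config(admin_censor_years = NaN),
               class = "bioagerisk_config_error")
  expect_error(simulation_config(allele_freqs = rep(0.3, 30)),  # length clash
               class = "bioagerisk_config_error")
  bad <- default_biomarker_specs()
  bad$s[3] <- 0
  expect_error(simulation_config(biomarker_specs = bad),
               class = "bioagerisk_config_error")
})

test_that("no-hazard limit yields a fully censored cohort", {
  cfg <- simulation_config(
    n_participants = 500, seed = 3,
    hazard_params = list(baseline_rate = 0, loghr_age = 0, loghr_accel = 0,
                         loghr_prs = 0, loghr_packyear = 0),
    death_rate = 0, target_incidence = NULL)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$aaa_event), 0)
  expect_equal(sum(co$death_event), 0)
  expect_true(all(co$time_years == cfg$admin_censor_years))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(n_participants = 800, seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  other <- simulate_cohort(simulation_config(n_participants = 800, seed = 10))
  expect_false(identical(other$crp, simulate_cohort(cfg)$crp))
})

test_that("observed incidence matches the configured target at study scale", {
  cfg <- simulation_config(n_participants = 20000, seed = 77)
  co <- simulate_cohort(cfg)
  target <- cfg$target_incidence
  se <- sqrt(target * (1 - target) / nrow(co))
  expect_lt(abs(mean(co$aaa_event) - target), 3 * se)
  # competing events and censoring are mutually exclusive states
  expect_true(all(co$aaa_event + co$death_event <= 1))
  expect_true(all(co$time_years >= 0 &
                    co$time_years <= cfg$admin_censor_years))
  expect_true(all(co$chronological_age >= cfg$age_range[1] &
                    co$chronological_age <= cfg$age_range[2]))
})

test_that("marginal structure is recovered at n = 50,000", {
  co <- big_cohort()
  cfg <- attr(co, "truth")$config
  spec <- cfg$biomarker_specs
  for (b in spec$biomarker) {
    fit <- lm(co[[b]] ~ co$chronological_age)
    est <- summary(fit)$coefficients[2, ]
    expect_lt(abs(est["Estimate"] - spec[b, "k"]), 3 * est["Std. Error"],
              label = paste("age slope of", b))
  }
  for (j in seq_len(cfg$n_snps)) {
    d <- co[[sprintf("snp%02d", j)]]
    f <- cfg$allele_freqs[j]
    se <- sqrt(2 * f * (1 - f) / length(d))
    expect_lt(abs(mean(d) - 2 * f), 3 * se, label = paste("snp", j))
  }
  # smoker mass point matches the configured never-smoker fraction
  p0 <- mean(co$pack_years == 0)
  expect_lt(abs(p0 - cfg$pack_years_p_zero), 3 * sqrt(0.25 / nrow(co)))
})

test_that("expected event count is monotone in the baseline rate", {
  counts <- sapply(c(1e-4, 3e-4, 1e-3, 3e-3), function(rate) {
    cfg <- simulation_config(
      n_participants = 4000, seed = 5,
      hazard_params = list(baseline_rate = rate, loghr_age = 0.09,
                           loghr_accel = 0.025, loghr_prs = 0.065,
                           loghr_packyear = 0.02),
      target_incidence = NULL)
    sum(simulate_cohort(cfg)$aaa_event)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("config and truth serialize and restore faithfully", {
  cfg <- simulation_config(n_participants = 300, seed = 4)
  path <- tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$biomarker_specs, cfg$biomarker_specs)
  expect_equal(back$hazard_params, cfg$hazard_params)
  # a restored config regenerates the identical cohort
  expect_identical(simulate_cohort(back), simulate_cohort(cfg))

  co <- simulate_cohort(cfg)
  tpath <- tempfile(fileext = ".json")
  write_cohort_truth(co, tpath)
  truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  expect_equal(truth$gamma, attr(co, "truth")$gamma, tolerance = 1e-12)
  expect_equal(truth$baseline_rate_used,
               attr(co, "truth")$baseline_rate_used, tolerance = 1e-12)
})

test_that("true acceleration decomposes into smoking path plus noise", {
  co <- small_cohort(5000, seed = 21)
  tr <- attr(co, "truth")
  expect_equal(co$true_accel_smoking, tr$gamma * co$pack_years)
  resid <- co$true_acceleration - co$true_accel_smoking
  # noise projection is centered and independent of pack-years
  expect_lt(abs(mean(resid)), 0.1)
  expect_lt(abs(cor(resid, co$pack_years)), 0.05)
})
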