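test_that("RERI/AP formula layer matches hand arithmetic", {
  r <- reri_ap(hr10 = 2, hr01 = 3, hr11 = 6)
  expect_equal(r$reri, 2)
  expect_equal(r$ap, 1 / 3)
  null <- reri_ap(1, 1, 1)
  expect_equal(null$reri, 0)
  expect_equal(null$ap, 0)
})

test_that("joint classification orders levels with the double-reference first", {
  g <- build_joint_groups(c(FALSE, TRUE, FALSE, TRUE),
                          c("low", "high", "intermediate", "low"))
  expect_equal(levels(g)[1], "nonaccel.low")
  expect_equal(levels(g)[6], "accel.high")
  expect_equal(as.character(g),
               c("nonaccel.low", "accel.high", "nonaccel.intermediate",
                 "accel.low"))
  q <- build_joint_quartile_groups(c(1, 4), c("low", "high"))
  expect_equal(levels(q)[1], "Q1.low")
  expect_equal(length(levels(q)), 12)
  expect_equal(as.character(q[2]), "Q4.high")
})

test_that("additive interaction is estimated from the 4-level cross-classification", {
  set.seed(51)
  dat <- sim_cell_surv(20000, hr10 = 2, hr01 = 2, hr11 = 6)
  res <- estimate_additive_interaction(dat, "exposed", "highrisk",
                                       n_boot = 50, seed = 5)
  # truth: RERI = 6 - 2 - 2 + 1 = 3 on the rate scale
  expect_equal(res$reri, 3, tolerance = 0.35 * 3)
  expect_equal(res$ap, res$reri / res$hr11, tolerance = 1e-12)
  expect_gt(res$reri_ci[1], 0)
  # same seed reproduces the bootstrap exactly
  res2 <- estimate_additive_interaction(dat, "exposed", "highrisk",
                                        n_boot = 50, seed = 5)
  expect_identical(res$reri_ci, res2$reri_ci)
  # empty cross-class cell is a named estimation error
  tiny <- dat[dat$exposed == 0 | dat$highrisk == 0, ]
  expect_error(
    estimate_additive_interaction(tiny, "exposed", "highrisk", n_boot = 0),
    "e1g1", class = "bioagerisk_estimation_error")
})

test_that("multiplicative interaction LRT behaves at the null and boundary", {
  set.seed(52)
  dat <- sim_cell_surv(8000, hr10 = 2, hr01 = 2, hr11 = 4)  # exactly multiplicative
  out <- test_multiplicative_interaction(dat, "exposed", "highrisk")
  expect_equal(out$df, 1)
  expect_gt(out$p, 0.001)
  # strong product term
  strong <- sim_cell_surv(8000, hr10 = 1.2, hr01 = 1.2, hr11 = 6)
  expect_lt(test_multiplicative_interaction(strong, "exposed",
                                            "highrisk")$p, 0.05)
  # aliased product term (risk never varies within exposure): df 0, p 1
  dat0 <- dat
  dat0$highrisk <- dat0$exposed
  out0 <- test_multiplicative_interaction(dat0, "exposed", "highrisk")
  expect_equal(out0$df, 0)
  expect_equal(out0$p, 1)
})

test_that("proportion mediated is the definitional identity of IE and DE", {
  expect_equal(proportion_mediated(7.42e-06, 7.11e-05),
               7.42e-06 / (7.42e-06 + 7.11e-05), tolerance = 1e-12)
  expect_warning(proportion_mediated(-1e-6, 1e-5), "opposite")
})

test_that("mediation point estimates satisfy their identities on a small cohort", {
  co <- small_cohort(4000, seed = 61)
  kdm <- kdm_age(co)
  co$kdm_accel <- compute_acceleration(kdm$kdm_age,
                                       co$chronological_age)$acceleration
  med <- run_mediation(co, "pack_years", "kdm_accel",
                       c("chronological_age", "sex"),
                       n_sims = 20, n_draws = 20, seed = 3)
  expect_equal(med$proportion_mediated,
               med$ie / (med$ie + med$de), tolerance = 1e-12)
  expect_equal(length(med$ie_ci), 2)
  # same seed reproduces bootstrap intervals exactly
  med2 <- run_mediation(co, "pack_years", "kdm_accel",
                        c("chronological_age", "sex"),
                        n_sims = 20, n_draws = 20, seed = 3)
  expect_identical(med$prop_ci, med2$prop_ci)
})

test_that("a generator without a smoking-to-biomarker path yields no indirect effect", {
  spec <- default_biomarker_specs()
  spec$smoking_slope <- 0
  co <- simulate_cohort(simulation_config(
    n_participants = 20000, seed = 62, biomarker_specs = spec,
    target_incidence = 0.02))
  kdm <- kdm_age(co)
  co$kdm_accel <- compute_acceleration(kdm$kdm_age,
                                       co$chronological_age)$acceleration
  med <- run_mediation(co, "pack_years", "kdm_accel",
                       c("chronological_age", "sex"),
                       n_sims = 40, n_draws = 20, seed = 4)
  expect_lt(abs(med$proportion_mediated), 0.05)
  expect_gt(med$p, 0.05)
})
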