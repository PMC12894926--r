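test_that("per-SD scaling is an exact reparameterization", {
  set.seed(41)
  dat <- sim_exp_surv(3000, loghr = 0.3, x = rnorm(3000, 0, 2.5))
  raw <- fit_cox(dat, "x", exposure_type = "continuous")
  scaled <- fit_cox(dat, "x", exposure_type = "per_sd")
  expect_equal(scaled$terms$loghr[1], raw$terms$loghr[1] * sd(dat$x),
               tolerance = 1e-8)
})

test_that("null exposure gives hazard ratio near 1", {
  set.seed(42)
  dat <- sim_exp_surv(5000, loghr = 0)
  fit <- fit_cox(dat, "x")
  expect_lt(abs(fit$terms$loghr[1]), 3 * fit$terms$se[1])
  expect_true(fit$terms$lo[1] < 1 && fit$terms$hi[1] > 1)
})

test_that("quartile boundaries follow the sample-quantile convention", {
  expect_equal(quartile_index(1:8), c(1, 1, 2, 2, 3, 3, 4, 4))
  set.seed(2)
  x <- rnorm(1000)
  q <- quartile_index(x)
  expect_true(all(table(q) == 250))
})

test_that("trend test detects a monotone effect and respects the null", {
  set.seed(43)
  x <- rnorm(8000)
  dat <- sim_exp_surv(8000, loghr = 0.4, x = x)
  tr <- quartile_trend_test(dat, "x")
  expect_lt(tr$p_trend, 0.05)
  expect_gt(tr$loghr_per_quartile, 0)
  null <- sim_exp_surv(8000, loghr = 0, x = rnorm(8000))
  expect_gt(quartile_trend_test(null, "x")$p_trend, 0.001)
})

test_that("restricted cubic basis is linear in the tails and errors on ties", {
  knots <- c(-1, 0, 1)
  # left of the first knot the restricted term vanishes identically
  b <- rcs_basis(c(-5, -3, 3, 4, 5), knots)
  expect_equal(unname(b[1:2, 2]), c(0, 0))
  # right of the last knot the restricted term is linear: equal differences
  expect_equal(b[4, 2] - b[3, 2], b[5, 2] - b[4, 2], tolerance = 1e-10)
  # inside the knot span it is genuinely cubic (second differences vary)
  bi <- rcs_basis(seq(-0.9, 0.9, by = 0.2), knots)
  d2 <- diff(diff(bi[, 2]))
  expect_gt(max(abs(diff(d2))), 1e-6)
  expect_error(rcs_basis(1:10, c(1, 1, 2)), class = "bioagerisk_knot_error")
})

test_that("dose-response curve is anchored at HR = 1 at the reference", {
  set.seed(44)
  dat <- sim_exp_surv(6000, loghr = 0.3, x = rnorm(6000))
  dr <- rcs_dose_response(dat, "x", grid = c(-1, median(dat$x), 1))
  at_ref <- dr$curve[dr$curve$exposure == dr$ref, ]
  expect_equal(at_ref$hr, 1, tolerance = 1e-12)
  expect_equal(at_ref$lo, 1, tolerance = 1e-12)
  expect_lt(dr$p_overall, 0.05)          # linear effect is detected
  expect_gt(dr$p_nonlinear, 0.001)       # no spurious curvature claimed
  expect_equal(dr$knots,
               quantile(dat$x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
})

test_that("proportional hazards diagnostics flag time-varying effects", {
  set.seed(45)
  ph_ok <- sim_exp_surv(4000, loghr = 0.5)
  fit <- fit_cox(ph_ok, "x")
  z <- test_proportional_hazards(fit)
  expect_true(all(c("x", "GLOBAL") %in% z$term))
  expect_gt(z$p[z$term == "x"], 0.001)
  tv <- sim_tv_surv(10000, beta = 0.5)
  # the PH-violating fit is deliberately misspecified; its convergence
  # grumbles are not under test
  ztv <- test_proportional_hazards(suppressWarnings(fit_cox(tv, "x")))
  expect_lt(ztv$p[ztv$term == "x"], 0.05)
  # degenerate input
  one <- sim_exp_surv(50, loghr = 0)
  one$aaa_event <- 0L; one$aaa_event[1] <- 1L
  expect_error(
    test_proportional_hazards(suppressWarnings(fit_cox(one, "x"))),
    class = "bioagerisk_degenerate_design_error")
})

test_that("Fine-Gray equals cause-specific Cox without competing deaths", {
  co <- small_cohort(4000, seed = 19, death_rate = 0)
  co$exposed <- co$true_acceleration > 0
  cs <- fit_cox(co, "exposed", "chronological_age", "binary")
  fg <- fit_fine_gray(co, "exposed", "chronological_age", "binary")
  expect_equal(fg$terms$loghr, cs$terms$loghr, tolerance = 1e-6)
  no_events <- co; no_events$aaa_event <- 0L
  expect_error(fit_fine_gray(no_events, "exposed", character(), "binary"),
               class = "bioagerisk_size_error")
})

test_that("heavy exposure-correlated mortality attenuates the subdistribution HR", {
  set.seed(46)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  ta <- rexp(n, 0.004 * exp(0.6 * x))
  td <- rexp(n, 0.05 * exp(1.2 * x))   # death strongly tied to exposure
  cens <- 12
  co <- data.frame(
    x = x,
    time_years = pmin(ta, td, cens),
    aaa_event = as.integer(ta <= td & ta < cens),
    death_event = as.integer(td < ta & td < cens))
  cs <- fit_cox(co, "x")
  fg <- fit_fine_gray(co, "x")
  expect_lt(fg$terms$loghr[1], cs$terms$loghr[1])
})

test_that("landmark filtering removes early follow-up and shifts time", {
  toy <- data.frame(time_years = c(1, 5), aaa_event = c(1, 1))
  out <- landmark_filter(toy, 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$time_years, 3)
  expect_identical(landmark_filter(toy, 0), toy)
  expect_warning(landmark_filter(data.frame(time_years = c(0.5, 1),
                                            aaa_event = c(1, 0)), 2),
                 "every participant")
})

test_that("complete-case filtering reproduces the never-missing fit", {
  co <- small_cohort(3000, seed = 23)
  co$exposed <- co$true_acceleration > 0
  full <- co[101:3000, ]
  holed <- co
  holed$bmi[1:100] <- NA
  cc <- holed[complete.cases(holed[, c("bmi", "chronological_age")]), ]
  f1 <- fit_cox(cc, "exposed", c("chronological_age", "bmi"), "binary")
  f2 <- fit_cox(full, "exposed", c("chronological_age", "bmi"), "binary")
  expect_equal(f1$terms$loghr, f2$terms$loghr, tolerance = 1e-12)
})
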