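test_that("KDM fitting recovers the generating slopes at n = 50,000", {
  co <- big_cohort()
  spec <- attr(co, "truth")$config$biomarker_specs
  for (sx in c("female", "male")) {
    model <- fit_kdm_model(co, sx)
    idx <- co$sex == sx
    for (b in kdm_biomarkers()) {
      se <- summary(lm(co[[b]][idx] ~ co$chronological_age[idx])
                    )$coefficients[2, "Std. Error"]
      expect_lt(abs(model$k[[b]] - spec[b, "k"]), 3 * se,
                label = paste(sx, b))
    }
    expect_gt(model$s_ba, 0)
  }
  # deterministic: same data, same model
  expect_identical(fit_kdm_model(co, "male"), fit_kdm_model(co, "male"))
})

test_that("noise-free training collapses s_i to 0 and s_BA to sd(CA)", {
  set.seed(8)
  n <- 500
  ca <- runif(n, 40, 70)
  spec <- default_biomarker_specs()
  co <- data.frame(chronological_age = ca,
                   sex = factor(rep("male", n),
                                levels = c("female", "male")))
  for (b in kdm_biomarkers()) {
    co[[b]] <- spec[b, "q"] + spec[b, "k"] * ca  # zero-noise biomarkers
  }
  m <- suppressWarnings(fit_kdm_model(co, "male"))  # perfect-fit lm warnings
  expect_true(all(m$s < 1e-8))
  expect_equal(m$s_ba, sd(ca), tolerance = 1e-6)
  # inputs on the biomarker-age line return the age itself
  probe <- sapply(kdm_biomarkers(),
                  function(b) spec[b, "q"] + spec[b, "k"] * 55)
  expect_equal(predict_kdm_age(m, probe, 55), 55, tolerance = 1e-6)
})

test_that("KDM estimator evaluates the closed form", {
  one <- structure(list(sex = "male", biomarkers = "b", q = c(b = 0),
                        k = c(b = 1), s = c(b = 1), s_ba = 1),
                   class = "kdm_model")
  # hand evaluation: (60*1 + 50*1) / (1 + 1)
  expect_equal(predict_kdm_age(one, c(b = 60), 50), 55)
  # s_BA -> Inf limit: pure biomarker prediction (x - q) / k
  lim <- structure(list(sex = "male", biomarkers = "b", q = c(b = 10),
                        k = c(b = 2), s = c(b = 1), s_ba = 1e12),
                   class = "kdm_model")
  expect_equal(predict_kdm_age(lim, c(b = 90), 0), 40, tolerance = 1e-6)
  expect_equal(predict_kdm_age(lim, c(b = 90), 80), 40, tolerance = 1e-6)
  expect_error(predict_kdm_age(one, c(b = NA_real_), 50),
               class = "bioagerisk_incomplete_input_error")
})

test_that("KDM noise-free identity holds for random models and ages", {
  set.seed(15)
  for (i in 1:50) {
    p <- sample(3:9, 1)
    nm <- paste0("b", seq_len(p))
    m <- structure(list(
      sex = "female", biomarkers = nm,
      q = setNames(rnorm(p, 50, 20), nm),
      k = setNames(runif(p, 0.05, 2) * sample(c(-1, 1), p, TRUE), nm),
      s = setNames(runif(p, 0.5, 10), nm),
      s_ba = runif(1, 2, 20)), class = "kdm_model")
    a <- runif(1, 30, 90)
    x <- m$q + m$k * a
    expect_equal(predict_kdm_age(m, x, a), a, tolerance = 1e-9)
  }
})

test_that("phenotypic age reproduces the high-precision golden evaluation", {
  ref <- data.frame(albumin = 45, creatinine = 70, glucose = 5, crp = 1,
                    lymph_pct = 30, mcv = 90, rdw = 13, alp = 70, wbc = 6)
  out <- compute_phenoage(ref, ca = 60)
  # frozen from a 50-digit evaluation of the printed closed form
  expect_equal(out$xb, -8.1397, tolerance = 1e-12)
  expect_equal(out$mortality_risk, 0.05590964631730157, tolerance = 1e-9)
  expect_equal(out$phenoage, 53.63358398064026, tolerance = 1e-9)
})

test_that("phenotypic age internal structure and domain handling", {
  ref <- data.frame(albumin = 45, creatinine = 70, glucose = 5, crp = 1,
                    lymph_pct = 30, mcv = 90, rdw = 13, alp = 70, wbc = 6)
  a60 <- compute_phenoage(ref, 60)
  a61 <- compute_phenoage(ref, 61)
  expect_gt(a61$phenoage, a60$phenoage)  # increasing in chronological age
  # re-evaluating the age transform from the returned risk is consistent
  g <- phenoage_coefficients()$gompertz
  expect_equal(a60$phenoage,
               as.numeric(g["age_intercept"] +
                            log(-g["g_scale"] * log(1 - a60$mortality_risk)) /
                            g["age_rate"]),
               tolerance = 1e-9)
  # risk is a probability and the score stays finite and monotone over a
  # wide input range (the upper tail rounds to risk = 1 in doubles but the
  # age transform is evaluated stably)
  ages <- seq(-150, 130, by = 20)
  out <- compute_phenoage(ref[rep(1, length(ages)), ], ages)
  expect_true(all(out$mortality_risk > 0 & out$mortality_risk <= 1))
  expect_true(all(is.finite(out$phenoage)))
  expect_true(all(diff(out$phenoage) > 0))
  # CRP floor and the domain error without it
  low <- ref; low$crp <- -1
  expect_equal(compute_phenoage(low, 60),
               compute_phenoage(transform(ref, crp = 0.01), 60))
  expect_error(compute_phenoage(low, 60, crp_floor = NULL),
               class = "bioagerisk_domain_error")
  # extreme xb overflows to risk = 1 and is reported as such
  hot <- ref; hot$rdw <- 1e4
  expect_error(compute_phenoage(hot, 60),
               class = "bioagerisk_overflow_error")
})

test_that("acceleration residuals follow the hand-computed 3-point OLS", {
  # OLS through (50,50),(60,62),(70,68): slope 0.9, intercept 6
  res <- compute_acceleration(c(50, 62, 68), c(50, 60, 70))
  expect_equal(res$acceleration, c(-1, 2, -1), tolerance = 1e-12)
  expect_equal(res$accelerated, c(FALSE, TRUE, FALSE))
})

test_that("acceleration residual properties", {
  # identity line: all residuals zero, zero is non-accelerated
  ident <- compute_acceleration(c(40, 50, 60), c(40, 50, 60))
  expect_equal(ident$acceleration, c(0, 0, 0), tolerance = 1e-12)
  expect_false(any(ident$accelerated))
  set.seed(33)
  ca <- runif(300, 40, 70)
  ba <- ca + rnorm(300, 0, 3)
  r <- compute_acceleration(ba, ca)
  expect_lt(abs(mean(r$acceleration)), 1e-8 * sd(ba))
  expect_lt(abs(cor(r$acceleration, ca)), 1e-8)
  expect_error(compute_acceleration(1:4, 1:5),
               class = "bioagerisk_shape_error")
})

test_that("pipeline-level acceleration distribution is centered near zero", {
  co <- small_cohort(4000, seed = 14)
  kdm <- kdm_age(co)
  acc <- compute_acceleration(kdm$kdm_age, co$chronological_age)
  expect_lt(abs(mean(acc$acceleration)), 1e-8)
  ph <- compute_phenoage(co, co$chronological_age)
  accp <- compute_acceleration(ph$phenoage, co$chronological_age)
  expect_lt(abs(mean(accp$acceleration)), 1e-8)
})
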