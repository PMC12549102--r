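test_that("behavior scores match the instrument's printed moments and range", {
  b <- behavior_spec("SSAI", mean = 26.66, sd = 6.72, floor = 20, ceiling = 80)
  s <- generate_behavior(b, 2000, seed = 11)
  expect_true(all(s >= 20 & s <= 80))
  expect_lt(abs(mean(s) - 26.66), 0.5)
  expect_lt(abs(sd(s) - 6.72), 0.5)
})

test_that("behavior generator handles degenerate and empty draws", {
  b0 <- behavior_spec("X", mean = 10, sd = 0, floor = 0, ceiling = 40)
  expect_equal(generate_behavior(b0, 5, seed = 1), rep(10, 5))
  b <- behavior_spec("X", mean = 10, sd = 2, floor = 0, ceiling = 40)
  expect_identical(generate_behavior(b, 0, seed = 1), numeric(0))
  expect_error(behavior_spec("X", mean = 10, sd = -1, floor = 0, ceiling = 40),
               "sd")
  expect_error(behavior_spec("X", mean = 50, sd = 1, floor = 0, ceiling = 40),
               "floor")
})

test_that("time series realize the planted block correlations", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 20, n_modules = 4,
                      n_volumes = 10000, within_module_r = 0.4,
                      between_module_r = 0.05, seed = 5)
  ts <- generate_timeseries(spec, 1)
  r <- cor(t(ts))
  assign <- planted_modules(20, 4)
  within <- r[outer(assign, assign, "==") & upper.tri(r)]
  between <- r[outer(assign, assign, "!=") & upper.tri(r)]
  expect_lt(max(abs(within - 0.4)), 0.03)
  expect_lt(max(abs(between - 0.05)), 0.05)
})

test_that("uncorrelated and single-module specs behave as limits", {
  spec0 <- cohort_spec(n_subjects = 1, n_rois = 10, n_modules = 2,
                       n_volumes = 4000, within_module_r = 0,
                       between_module_r = 0, seed = 6)
  r0 <- cor(t(generate_timeseries(spec0, 1)))
  off <- abs(r0[upper.tri(r0)])
  expect_gt(mean(off < 3 / sqrt(4000)), 0.95)
  spec1 <- cohort_spec(n_subjects = 1, n_rois = 8, n_modules = 1,
                       n_volumes = 6000, within_module_r = 0.3, seed = 7)
  r1 <- cor(t(generate_timeseries(spec1, 1)))
  expect_lt(max(abs(r1[upper.tri(r1)] - 0.3)), 0.05)
})

test_that("cohort spec rejects invalid parameters", {
  expect_error(cohort_spec(n_modules = 0), "n_modules")
  expect_error(cohort_spec(n_modules = 101, n_rois = 100), "n_modules")
  expect_error(cohort_spec(within_module_r = 1), "strictly")
  expect_error(cohort_spec(motion_spike_prob = 1.2), "spike_prob")
  bad_effect <- effect_spec("STAI", matrix(c(1, 999), 1), 0.01)
  expect_error(cohort_spec(effect_specs = list(bad_effect)), "ROI range")
  expect_error(effect_spec("STAI", matrix(c(3, 3), 1), 0.01), "distinct")
  expect_error(effect_spec("STAI", rbind(c(1, 2), c(2, 1)), 0.01), "unique")
})

test_that("planted behavior effects are recoverable at the generating slope", {
  ef <- effect_spec("STAI", matrix(c(1, 6), 1), slope_per_unit = 0.005,
                    base_r = 0.1)
  spec <- cohort_spec(n_subjects = 500, n_rois = 10, n_modules = 2,
                      n_volumes = 2000, motion_spike_prob = 0,
                      effect_specs = list(ef), seed = 21)
  co <- simulate_cohort(spec)
  r_edge <- vapply(co$subjects,
                   function(s) cor(s$timeseries[1, ], s$timeseries[6, ]),
                   numeric(1))
  slope <- unname(coef(lm(r_edge ~ co$covariates$STAI))[2])
  expect_lt(abs(slope - 0.005), 0.0025)  # within 50% of the generating slope
})

test_that("zero slope leaves edge correlations independent of the score", {
  ef <- effect_spec("STAI", matrix(c(1, 6), 1), slope_per_unit = 0, base_r = 0.2)
  spec <- cohort_spec(n_subjects = 200, n_rois = 8, n_modules = 2,
                      n_volumes = 400, motion_spike_prob = 0,
                      effect_specs = list(ef), seed = 22)
  co <- simulate_cohort(spec)
  r_edge <- vapply(co$subjects,
                   function(s) cor(s$timeseries[1, ], s$timeseries[6, ]),
                   numeric(1))
  fit <- summary(lm(r_edge ~ co$covariates$STAI))
  expect_lt(abs(fit$coefficients[2, 1]), 2 * fit$coefficients[2, 2])
})

test_that("extreme effect targets are clipped at |r| = 0.9", {
  ef <- effect_spec("STAI", matrix(c(1, 2), 1), slope_per_unit = 1, base_r = 0.88)
  spec <- cohort_spec(n_subjects = 8, n_rois = 6, n_modules = 2,
                      n_volumes = 20000, motion_spike_prob = 0,
                      effect_specs = list(ef), seed = 23)
  co <- simulate_cohort(spec)
  # subject with the highest score: target 0.88 + slope * delta >> 0.9 -> 0.9
  top <- which.max(co$covariates$STAI)
  r_top <- cor(co$subjects[[top]]$timeseries[1, ], co$subjects[[top]]$timeseries[2, ])
  expect_lt(abs(r_top - 0.9), 0.03)
  expect_lt(r_top, 0.95)
})

test_that("motion traces honor the spike probability", {
  m0 <- generate_motion_trace(200, spike_prob = 0, seed = 1)
  expect_true(all(m0$trans_delta_mm <= 1 & m0$rot_delta_deg <= 1.5))
  m1 <- generate_motion_trace(200, spike_prob = 1, seed = 2)
  expect_true(all(m1$trans_delta_mm > 1 | m1$rot_delta_deg > 1.5))
  m <- generate_motion_trace(10000, spike_prob = 0.1, seed = 3)
  frac <- mean(m$trans_delta_mm > 1 | m$rot_delta_deg > 1.5)
  expect_lt(abs(frac - 0.1), 0.01)
  expect_error(generate_motion_trace(10, spike_prob = 1.5), "spike_prob")
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  spec <- cohort_spec(n_subjects = 4, n_rois = 10, n_modules = 2,
                      n_volumes = 30, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$subjects[[3]]$timeseries, b$subjects[[3]]$timeseries)
  expect_identical(a$subjects[[2]]$translation_delta,
                   b$subjects[[2]]$translation_delta)
})

test_that("cohorts round-trip through the plain-text writers", {
  spec <- cohort_spec(n_subjects = 2, n_rois = 5, n_modules = 2,
                      n_volumes = 12, seed = 4)
  co <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ts <- as.matrix(read.table(file.path(dir, "scan001_timeseries.tsv"),
                             row.names = 1, sep = "\t"))
  expect_equal(unname(ts), unname(co$subjects[[1]]$timeseries), tolerance = 1e-12)
  cov <- read.csv(file.path(dir, "covariates.csv"))
  expect_equal(cov$STAI, co$covariates$STAI, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$modules, co$truth$modules)
})
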