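test_that("Manhattan distances follow the L1 definition", {
  p <- rbind(s1 = c(0.1, 0.2), s2 = c(0.3, -0.1))
  d <- manhattan_distances(p)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  set.seed(51)
  q <- matrix(rnorm(40), 8)
  dq <- manhattan_distances(q)
  expect_equal(dq, t(dq))
  expect_true(all(dq >= 0))
  expect_equal(manhattan_distances(rbind(q[1, ], q[1, ]))[1, 2], 0)
  expect_error(manhattan_distances(rbind(c(1, NA), c(0, 0))), "missing")
})

test_that("Gower centering recovers the total sum of squares", {
  x <- c(0, 1, 2)
  g <- gower_center(as.matrix(dist(x)))
  expect_equal(sum(diag(g)), sum((x - mean(x))^2))  # = 2
  expect_equal(unname(rowSums(g)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(colSums(g)), rep(0, 3), tolerance = 1e-12)
  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4))
  set.seed(52)
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  expect_equal(unname(rowSums(gower_center(d))), rep(0, 10), tolerance = 1e-10)
})

test_that("MDMR on 1-D Euclidean distances reproduces classical regression", {
  set.seed(53)
  for (k in 1:10) {
    n <- 30
    y <- rnorm(n); x1 <- rnorm(n); x2 <- rnorm(n)
    d <- as.matrix(dist(y))
    res <- mdmr_fit(d, cbind(intercept = 1, x1 = x1, x2 = x2),
                    permutations = 19, seed = k)
    sm <- summary(lm(y ~ x1 + x2))
    expect_equal(res$pseudo_f[1], unname(sm$fstatistic[1]), tolerance = 1e-8)
    expect_equal(res$pseudo_r2[1], sm$r.squared, tolerance = 1e-8)
    # conditional factor F equals the classical partial (type III) F
    a <- anova(lm(y ~ x2 + x1))
    expect_equal(res$pseudo_f[res$factor == "x1"], a["x1", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("MDMR omnibus agrees with vegan's PERMANOVA on real distances", {
  skip_if_not_installed("vegan")
  set.seed(54)
  n <- 25
  y <- matrix(rnorm(n * 6), n)
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- manhattan_distances(y)
  res <- mdmr_fit(d, cbind(intercept = 1, x1 = x1, x2 = x2),
                  permutations = 19, seed = 1)
  ado <- vegan::adonis2(as.dist(d) ~ x1 + x2,
                        data = data.frame(x1 = x1, x2 = x2),
                        permutations = 19, by = NULL)
  expect_equal(res$pseudo_f[1], ado$F[1], tolerance = 1e-8)
  expect_equal(res$pseudo_r2[1], ado$R2[1], tolerance = 1e-8)
})

test_that("permutation p values attain the (b+1)/(B+1) floor under strong signal", {
  set.seed(55)
  n <- 24
  x <- rnorm(n)
  y <- 5 * x                        # perfectly explained response
  d <- as.matrix(dist(y))
  res <- mdmr_fit(d, cbind(intercept = 1, x = x), permutations = 49, seed = 2)
  expect_equal(res$p_perm[1], 1 / 50)
  expect_equal(res$p_perm[res$factor == "x"], 1 / 50)
  expect_error(mdmr_fit(d, cbind(intercept = 1, x = x), permutations = 0),
               "permutations")
})

test_that("pseudo-F is invariant to distance scaling and subject relabeling", {
  set.seed(56)
  n <- 20
  y <- matrix(rnorm(n * 4), n)
  x <- cbind(intercept = 1, a = rnorm(n))
  d <- manhattan_distances(y)
  f1 <- mdmr_fit(d, x, permutations = 9, seed = 1)$pseudo_f[1]
  f3 <- mdmr_fit(3 * d, x, permutations = 9, seed = 1)$pseudo_f[1]
  expect_equal(f1, f3, tolerance = 1e-10)
  p <- sample(n)
  fp <- mdmr_fit(d[p, p], x[p, , drop = FALSE], permutations = 9, seed = 1)$pseudo_f[1]
  expect_equal(f1, fp, tolerance = 1e-10)
})

test_that("null permutation p values are uniform", {
  set.seed(57)
  pvals <- replicate(300, {
    n <- 20
    y <- matrix(rnorm(n * 3), n)
    x <- cbind(intercept = 1, a = rnorm(n))
    mdmr_fit(manhattan_distances(y), x, factors = character(0),
             permutations = 99, seed = sample.int(1e6, 1))$p_perm[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("mean pseudo-F grows monotonically with the planted slope", {
  slopes <- c(0, 0.005, 0.02)
  mean_f <- vapply(slopes, function(sl) {
    fs <- vapply(1:8, function(k) {
      ef <- effect_spec("STAI", as.matrix(expand.grid(1:3, 4:6)),
                        slope_per_unit = sl, base_r = 0.1)
      spec <- cohort_spec(n_subjects = 30, n_rois = 8, n_modules = 2,
                          n_volumes = 120, motion_spike_prob = 0,
                          effect_specs = list(ef), seed = 7000 + 100 * sl * 1000 + k)
      ce <- cohort_edges(spec)
      x <- build_design(ce$covariates, "STAI")
      mdmr_fit(manhattan_distances(ce$edges), x, factors = character(0),
               permutations = 1, seed = k)$pseudo_f[1]
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  expect_true(all(diff(mean_f) > 0))
})

test_that("design construction and scanning enforce their contracts", {
  cov <- data.frame(a = rnorm(10), b = rnorm(10))
  x <- build_design(cov, c("a", "b"))
  expect_equal(colnames(x), c("intercept", "a", "b"))
  expect_error(build_design(cov, "missing_col"), "missing")
  cov$c <- cov$a
  expect_error(build_design(cov, c("a", "c")), "rank")
  edges <- random_edges(12, 5, seed = 58)
  xs <- cbind(intercept = 1, a = rnorm(12))
  per_roi <- cwas_scan(edges, xs, mode = "per_roi", permutations = 9, seed = 1,
                       labels = roi_labels(5))
  expect_equal(sum(per_roi$factor == "omnibus"), 5)  # one omnibus row per ROI
  whole <- cwas_scan(edges, xs, mode = "whole_connectome", permutations = 9,
                     seed = 1)
  expect_equal(unique(whole$unit), "whole_connectome")
  expect_error(cwas_scan(edges[1, , drop = FALSE], xs[1, , drop = FALSE]),
               "2 subjects")
})

test_that("per-ROI scans concentrate signal on the ROI carrying the effect", {
  # effect on every edge incident to ROI 2 of 10; that ROI should outrank
  # the rest in omnibus pseudo-F in most replicates
  hits <- vapply(1:8, function(k) {
    edges_eff <- cbind(rep(2, 9), setdiff(1:10, 2))
    ef <- effect_spec("STAI", edges_eff, slope_per_unit = 0.012, base_r = 0.1)
    spec <- cohort_spec(n_subjects = 40, n_rois = 10, n_modules = 2,
                        n_volumes = 120, motion_spike_prob = 0,
                        effect_specs = list(ef), seed = 8000 + k)
    ce <- cohort_edges(spec)
    x <- build_design(ce$covariates, "STAI")
    res <- cwas_scan(ce$edges, x, mode = "per_roi", factors = character(0),
                     permutations = 1, seed = k, labels = roi_labels(10))
    omn <- res[res$factor == "omnibus", ]
    which.max(omn$pseudo_f) == 2
  }, logical(1))
  expect_gte(sum(hits), 6)
})

test_that("marginal screening keeps informative covariates and drops noise", {
  set.seed(59)
  n <- 40
  y <- rnorm(n)
  d <- as.matrix(dist(y))
  cov <- data.frame(signal = y + rnorm(n, sd = 0.3), noise = rnorm(n))
  sc <- screen_covariates(d, cov, c("signal", "noise"), keep_threshold = 0.10,
                          permutations = 199, seed = 3)
  expect_true(sc$keep[sc$covariate == "signal"])
  expect_false(sc$keep[sc$covariate == "noise"])
})
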