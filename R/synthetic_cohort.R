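#' Behavior score specification
#'
#' Describes one questionnaire instrument as a truncated normal: scores are
#' drawn from N(mean, sd) and constrained to the instrument's floor/ceiling.
#' Defaults for the four instruments used in the workflow are provided by
#' [default_behavior_specs()].
#'
#' @param name Instrument label, e.g. "SSAI".
#' @param mean,sd Population mean and SD of the untruncated normal.
#' @param floor,ceiling Instrument score range.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(name, mean, sd, floor, ceiling) {
  if (sd < 0) stop("invalid behavior spec: sd must be >= 0")
  if (!(floor <= mean && mean <= ceiling))
    stop("invalid behavior spec: require floor <= mean <= ceiling")
  structure(list(name = name, mean = mean, sd = sd,
                 floor = floor, ceiling = ceiling),
            class = "behavior_spec")
}

#' Default questionnaire specifications
#'
#' Cohort-level means and SDs for the Spielberger state (SSAI) and trait
#' (STAI) anxiety inventories, the Perceived Stress Scale (PSS) and the
#' Edinburgh Postnatal Depression Scale (EPDS), at the values reported for
#' the pregnant cohort this workflow emulates, truncated to each
#' instrument's score range.
#'
#' @return Named list of [behavior_spec()] objects.
#' @export
default_behavior_specs <- function() {
  list(
    SSAI = behavior_spec("SSAI", mean = 26.66, sd = 6.72, floor = 20, ceiling = 80),
    STAI = behavior_spec("STAI", mean = 28.09, sd = 6.62, floor = 20, ceiling = 80),
    PSS  = behavior_spec("PSS",  mean = 9.27,  sd = 5.13, floor = 0,  ceiling = 40),
    EPDS = behavior_spec("EPDS", mean = 3.24,  sd = 2.84, floor = 0,  ceiling = 30)
  )
}

#' Planted edge-behavior effect
#'
#' Defines a set of edges whose population correlation varies linearly with a
#' behavior score: for subject i the target correlation of each listed edge is
#' `base_r + slope_per_unit * (score_i - mean(score))`, clipped to [-0.9, 0.9].
#'
#' @param behavior_name Name of the behavior driving the effect.
#' @param edges Two-column matrix or data.frame of ROI index pairs (i, j).
#' @param slope_per_unit Change in target correlation per score unit.
#' @param base_r Correlation at the mean score.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(behavior_name, edges, slope_per_unit, base_r = 0.2) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (any(edges[, 1] == edges[, 2])) stop("effect edges must join distinct ROIs")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stop("effect edges must be unique")
  structure(list(behavior_name = behavior_name, edges = edges,
                 slope_per_unit = slope_per_unit, base_r = base_r),
            class = "effect_spec")
}

#' Synthetic cohort specification
#'
#' Defaults emulate the study conditions the workflow targets: 59 scans,
#' 100 ROIs grouped in 14 modules, ~110 volumes at TR 3 s, block-structured
#' ROI correlations, and the four questionnaire instruments.
#'
#' @param n_subjects Number of scans.
#' @param n_rois Number of regions of interest.
#' @param n_modules Number of equal-size planted modules (remainder ROIs go
#'   to the last module).
#' @param n_volumes Volumes per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param within_module_r,between_module_r Population correlation inside /
#'   between modules.
#' @param behavior_specs List of [behavior_spec()] objects.
#' @param effect_specs List of [effect_spec()] objects (may be empty).
#' @param motion_spike_prob Per-volume probability of a motion spike.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 59, n_rois = 100, n_modules = 14,
                        n_volumes = 110, tr_seconds = 3,
                        within_module_r = 0.4, between_module_r = 0.05,
                        behavior_specs = default_behavior_specs(),
                        effect_specs = list(),
                        motion_spike_prob = 0.05, seed = 1L) {
  if (n_subjects < 0) stop("invalid cohort spec: n_subjects must be >= 0")
  if (n_modules < 1 || n_modules > n_rois)
    stop("invalid cohort spec: require 1 <= n_modules <= n_rois")
  if (abs(within_module_r) >= 1 || abs(between_module_r) >= 1)
    stop("invalid cohort spec: module correlations must lie strictly in (-1, 1)")
  if (motion_spike_prob < 0 || motion_spike_prob > 1)
    stop("invalid cohort spec: motion_spike_prob must be in [0, 1]")
  if (!is.null(names(behavior_specs)) || length(behavior_specs)) {
    nm <- vapply(behavior_specs, function(b) b$name, character(1))
    names(behavior_specs) <- nm
  }
  for (ef in effect_specs) {
    if (any(ef$edges < 1 | ef$edges > n_rois))
      stop("effect edges outside ROI range")
    if (!ef$behavior_name %in% names(behavior_specs))
      stop("effect references unknown behavior: ", ef$behavior_name)
  }
  structure(list(n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
                 n_modules = as.integer(n_modules), n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, within_module_r = within_module_r,
                 between_module_r = between_module_r,
                 behavior_specs = behavior_specs, effect_specs = effect_specs,
                 motion_spike_prob = motion_spike_prob, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Planted module assignment
#'
#' Equal-size contiguous blocks; remainder ROIs are assigned to the last
#' module.
#'
#' @param n_rois,n_modules Counts.
#' @return Integer vector of length `n_rois` with values in 1..n_modules.
#' @export
planted_modules <- function(n_rois, n_modules) {
  size <- n_rois %/% n_modules
  a <- rep(seq_len(n_modules), each = size)
  c(a, rep(n_modules, n_rois - length(a)))
}

# Population correlation matrix implied by the block structure, repaired to
# positive definiteness by eigenvalue clipping if needed.
block_correlation <- function(spec) {
  assign <- planted_modules(spec$n_rois, spec$n_modules)
  same <- outer(assign, assign, "==")
  r <- ifelse(same, spec$within_module_r, spec$between_module_r)
  diag(r) <- 1
  near_pd(r, eps = 1e-8, correlation = TRUE)
}

# Mean and SD of N(mu, sigma) truncated to [a, b] (closed form).
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  lam <- (stats::dnorm(al) - stats::dnorm(be)) / z
  del <- (ifelse(is.finite(al), al * stats::dnorm(al), 0) -
            ifelse(is.finite(be), be * stats::dnorm(be), 0)) / z - lam^2
  c(mean = mu + sigma * lam, sd = sigma * sqrt(1 + del))
}

# Underlying normal parameters whose truncation to [a, b] has the target
# mean and SD (moment matching, Nelder-Mead on (mu, log sigma)).
solve_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Draw truncated-normal behavior scores
#'
#' Scores follow a normal distribution truncated to the instrument's
#' `[floor, ceiling]` range. The underlying normal parameters are
#' moment-matched so that the *truncated* distribution has the requested mean
#' and SD (truncating N(mean, sd) directly would inflate the mean whenever
#' the floor cuts into the lower tail). Sampling is by inverse CDF, so the
#' draw is exact and reproducible under a fixed seed. With `sd = 0` every
#' score equals the mean.
#'
#' @param spec A [behavior_spec()].
#' @param n Number of scores.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` within `[floor, ceiling]`.
#' @export
generate_behavior <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "behavior_spec"))
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  if (spec$sd == 0) return(rep(spec$mean, n))
  par <- solve_truncnorm(spec$mean, spec$sd, spec$floor, spec$ceiling)
  with_seed(seed, {
    lo <- stats::pnorm(spec$floor, par["mu"], par["sigma"])
    hi <- stats::pnorm(spec$ceiling, par["mu"], par["sigma"])
    stats::qnorm(stats::runif(n, lo, hi), par["mu"], par["sigma"])
  })
}

#' Simulate one subject's ROI time series
#'
#' Zero-mean multivariate normal draws whose correlation matrix carries the
#' spec's block structure; an optional per-subject correlation matrix
#' (carrying planted behavior effects) can be supplied instead.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index 1-based subject number (seeds the draw).
#' @param sigma Optional correlation matrix overriding the block structure.
#' @return ROI x volume numeric matrix with ROI labels as rownames.
#' @export
generate_timeseries <- function(spec, subject_index, sigma = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(sigma)) sigma <- block_correlation(spec)
  seeds <- split_seed(spec$seed, spec$n_subjects + 10L)
  ts <- with_seed(seeds[subject_index],
                  MASS::mvrnorm(spec$n_volumes, mu = rep(0, spec$n_rois),
                                Sigma = sigma))
  ts <- t(ts)  # ROI x volume
  rownames(ts) <- roi_labels(spec$n_rois)
  ts
}

#' @rdname generate_timeseries
#' @export
roi_labels <- function(n_rois) sprintf("ROI%03d", seq_len(n_rois))

# Per-subject correlation matrix with behavior effects injected: target
# correlations of effect edges move linearly with the (centered) score and
# are clipped to [-0.9, 0.9] before positive-definite repair.
subject_sigma <- function(spec, scores_by_behavior, subject_index) {
  sigma <- block_correlation(spec)
  for (ef in spec$effect_specs) {
    s <- scores_by_behavior[[ef$behavior_name]]
    delta <- s[subject_index] - mean(s)
    target <- max(-0.9, min(0.9, ef$base_r + ef$slope_per_unit * delta))
    for (k in seq_len(nrow(ef$edges))) {
      i <- ef$edges[k, 1]; j <- ef$edges[k, 2]
      sigma[i, j] <- sigma[j, i] <- target
    }
  }
  if (length(spec$effect_specs)) sigma <- near_pd(sigma, 1e-8, correlation = TRUE)
  sigma
}

#' Simulate a per-volume motion trace
#'
#' Baseline jitter stays strictly below the censoring thresholds (1 mm,
#' 1.5 degrees); Bernoulli(`spike_prob`) spikes exceed one of them, so every
#' volume is unambiguously spike or non-spike.
#'
#' @param n_volumes Number of volumes.
#' @param spike_prob Per-volume spike probability.
#' @param seed Integer seed.
#' @return data.frame with columns `trans_delta_mm`, `rot_delta_deg`,
#'   `is_spike`.
#' @export
generate_motion_trace <- function(n_volumes, spike_prob, seed = 1L) {
  if (n_volumes < 0) stop("n_volumes must be >= 0")
  if (spike_prob < 0 || spike_prob > 1)
    stop("invalid spec: spike_prob must be in [0, 1]")
  with_seed(seed, {
    trans <- pmin(abs(stats::rnorm(n_volumes, 0, 0.15)), 0.9)
    rot <- pmin(abs(stats::rnorm(n_volumes, 0, 0.2)), 1.3)
    spike <- stats::runif(n_volumes) < spike_prob
    which_axis <- stats::runif(n_volumes) < 0.7  # spikes mostly translational
    trans[spike & which_axis] <- stats::runif(sum(spike & which_axis), 1.05, 2.5)
    rot[spike & !which_axis] <- stats::runif(sum(spike & !which_axis), 1.6, 3.0)
    data.frame(trans_delta_mm = trans, rot_delta_deg = rot, is_spike = spike)
  })
}

#' Simulate a full cohort
#'
#' Draws behavior scores for every instrument, builds per-subject correlation
#' matrices (injecting any planted effects), samples ROI time series and
#' motion traces, and packages everything with its ground truth. All
#' randomness flows from `spec$seed`; a fixed seed gives bit-identical
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements `subjects` (list of
#'   [subject_scan()]), `covariates` (data.frame of scores and scan metadata)
#'   and `truth` (module assignment, effect edges and slopes).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- split_seed(spec$seed, 2L * spec$n_subjects + length(spec$behavior_specs) + 4L)
  b_seeds <- seeds[seq_along(spec$behavior_specs)]
  m_seeds <- seeds[length(spec$behavior_specs) + seq_len(spec$n_subjects)]
  scores <- Map(function(b, s) generate_behavior(b, spec$n_subjects, s),
                spec$behavior_specs, as.list(b_seeds))
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sigma <- subject_sigma(spec, scores, i)
    ts <- generate_timeseries(spec, i, sigma = sigma)
    mt <- generate_motion_trace(spec$n_volumes, spec$motion_spike_prob, m_seeds[i])
    subjects[[i]] <- subject_scan(
      scan_id = sprintf("scan%03d", i), timeseries = ts,
      translation_delta = mt$trans_delta_mm, rotation_delta = mt$rot_delta_deg,
      tr_seconds = spec$tr_seconds)
  }
  cov <- data.frame(subject_id = sprintf("sub%03d", seq_len(spec$n_subjects)),
                    scan_id = sprintf("scan%03d", seq_len(spec$n_subjects)),
                    stringsAsFactors = FALSE)
  for (nm in names(scores)) cov[[nm]] <- scores[[nm]]
  cov$retained_volumes <- vapply(subjects, function(s) sum(s$keep_mask), integer(1))
  truth <- list(
    modules = planted_modules(spec$n_rois, spec$n_modules),
    effects = lapply(spec$effect_specs, function(ef)
      list(behavior = ef$behavior_name, edges = ef$edges,
           slope_per_unit = ef$slope_per_unit, base_r = ef$base_r)))
  structure(list(subjects = subjects, covariates = cov, truth = truth,
                 spec = spec), class = "cohort")
}

#' Write a cohort to plain-text files
#'
#' Per-subject time-series TSV (rows = ROIs, columns = volumes), motion-trace
#' TSVs, one covariate CSV and a ground-truth JSON.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    utils::write.table(s$timeseries,
                       file.path(dir, paste0(s$scan_id, "_timeseries.tsv")),
                       sep = "\t", quote = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(volume = seq_along(s$translation_delta),
                 trans_delta_mm = s$translation_delta,
                 rot_delta_deg = s$rotation_delta),
      file.path(dir, paste0(s$scan_id, "_motion.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param tr_seconds Repetition time to attach to the scans read back.
#' @export
read_cohort <- function(dir, tr_seconds = 3) {
  cov <- utils::read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  subjects <- lapply(cov$scan_id, function(id) {
    ts <- as.matrix(utils::read.table(
      file.path(dir, paste0(id, "_timeseries.tsv")), sep = "\t",
      row.names = 1))
    colnames(ts) <- NULL
    mt <- utils::read.table(file.path(dir, paste0(id, "_motion.tsv")),
                            sep = "\t", header = TRUE)
    subject_scan(id, ts, mt$trans_delta_mm, mt$rot_delta_deg, tr_seconds)
  })
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(subjects = subjects, covariates = cov, truth = truth),
            class = "cohort")
}
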