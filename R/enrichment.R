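#' Edge-level behavior correlations
#'
#' Pearson correlation of every edge's z values with a behavior score across
#' subjects; two-tailed p from the t distribution with n - 2 degrees of
#' freedom; an edge is significant when p < alpha (no multiple-testing
#' correction at the edge level).
#'
#' @param edges subject x edge matrix (canonical ordering, columns named
#'   `roi_i|roi_j`).
#' @param behavior Numeric score per subject.
#' @param alpha Edge significance threshold.
#' @return data.frame with one row per edge: `roi_i`, `roi_j`, `r`, `p`,
#'   `significant`, `direction` (sign of r).
#' @export
edge_behavior_correlations <- function(edges, behavior, alpha = 0.05) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (n < 4) stop("need at least 4 subjects")
  if (length(behavior) != n) stop("one behavior score per subject required")
  if (stats::sd(behavior) == 0) stop("behavior scores are constant")
  r <- edge_cor(edges, behavior)
  p <- edge_cor_p(r, n)
  pairs <- edge_pairs_from_names(colnames(edges), ncol(edges))
  data.frame(roi_i = pairs$roi_i, roi_j = pairs$roi_j, r = r, p = p,
             significant = p < alpha, direction = sign(r),
             stringsAsFactors = FALSE)
}

# correlation of one score vector with every column
edge_cor <- function(edges, behavior) as.numeric(stats::cor(behavior, edges))
edge_cor_p <- function(r, n) correlation_p(r, n)

#' Two-tailed p value of a Pearson correlation
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution with
#' n - 2 degrees of freedom, both tails.
#'
#' @param r Correlation(s).
#' @param n Number of paired observations.
#' @return Two-tailed p value(s).
#' @export
correlation_p <- function(r, n) {
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  2 * stats::pt(-abs(tt), df = n - 2)
}

edge_pairs_from_names <- function(nm, n_edges) {
  if (!is.null(nm) && all(grepl("|", nm, fixed = TRUE))) {
    sp <- strsplit(nm, "|", fixed = TRUE)
    return(list(roi_i = vapply(sp, `[`, "", 1), roi_j = vapply(sp, `[`, "", 2)))
  }
  n <- as.integer((1 + sqrt(1 + 8 * n_edges)) / 2)
  idx <- edge_index(roi_labels(n))
  list(roi_i = idx$roi_i, roi_j = idx$roi_j)
}

# Map every edge of an EdgeStats table (or roi_i/roi_j vectors) onto the
# K(K+1)/2 unordered module pairs; returns the integer pair index per edge
# plus the pair table skeleton.
pair_structure <- function(roi_i, roi_j, partition) {
  assign <- partition$assignment
  mi <- assign[roi_i]
  mj <- assign[roi_j]
  if (anyNA(mi) || anyNA(mj)) stop("edge ROI labels missing from the partition")
  a <- pmin(mi, mj); b <- pmax(mi, mj)
  k <- partition$n_modules
  grid <- expand.grid(module_a = seq_len(k), module_b = seq_len(k))
  grid <- grid[grid$module_a <= grid$module_b, ]
  ids <- paste(grid$module_a, grid$module_b, sep = "-")
  f <- match(paste(a, b, sep = "-"), ids)
  list(pair_of_edge = f, module_a = grid$module_a, module_b = grid$module_b,
       n_pairs = length(ids))
}

# 1-df Pearson chi-square (no continuity correction) for each pair's 2x2
# table in-pair/out-pair x significant/not, vectorized over pairs.
pair_chi2_values <- function(n_edges, obs, total_edges, total_sig) {
  a11 <- obs
  a12 <- n_edges - obs
  a21 <- total_sig - obs
  a22 <- (total_edges - n_edges) - a21
  num <- total_edges * (a11 * a22 - a12 * a21)^2
  den <- as.numeric(n_edges) * (total_edges - n_edges) *
    total_sig * (total_edges - total_sig)
  ifelse(den == 0, 0, num / den)
}

#' Network-pair enrichment chi-square
#'
#' Assigns every edge to one of the K(K+1)/2 unordered module pairs
#' (within-module pairs included) and asks, per pair, whether significant
#' edges concentrate there beyond a uniform spread: a 1-df Pearson
#' chi-square (no continuity correction) on the 2x2 table
#' in-pair/out-pair x significant/not. Expected counts assume significant
#' edges spread uniformly over edges. Enrichment is one-sided: a pair can
#' only be enriched when observed > expected.
#'
#' @param stats EdgeStats table from [edge_behavior_correlations()].
#' @param partition A `module_partition` from [detect_modules()].
#' @return data.frame with one row per module pair: `module_a`, `module_b`
#'   (a <= b), `n_edges`, `observed_significant`, `expected_significant`,
#'   `chi2`, `over_expected`.
#' @export
pair_chi2 <- function(stats, partition) {
  ps <- pair_structure(stats$roi_i, stats$roi_j, partition)
  n_edges <- tabulate(ps$pair_of_edge, nbins = ps$n_pairs)
  obs <- tabulate(ps$pair_of_edge[stats$significant], nbins = ps$n_pairs)
  total_edges <- nrow(stats)
  total_sig <- sum(stats$significant)
  expected <- total_sig * n_edges / total_edges
  data.frame(module_a = ps$module_a, module_b = ps$module_b,
             n_edges = n_edges, observed_significant = obs,
             expected_significant = expected,
             chi2 = pair_chi2_values(n_edges, obs, total_edges, total_sig),
             over_expected = obs > expected)
}

#' Permutation test of network-pair enrichment
#'
#' Re-runs the full edge screen under `permutations` permutations of the
#' behavior score (the whole pipeline is permuted, not just the counts) and
#' compares each pair against its permuted distribution one-sidedly, through
#' the signed statistic `T = chi2` when the pair is over-expected and
#' `T = -chi2` otherwise: `p_perm = (1 + #{T_perm >= T_obs}) / (B + 1)`.
#' For an over-expected pair this counts exactly the permutations that are
#' both over-expected and at least as extreme; under-expected pairs get
#' large p values and are never called enriched. A pair is enriched when
#' observed > expected and p_perm < alpha.
#'
#' @param edges subject x edge matrix.
#' @param behavior Score per subject.
#' @param partition A `module_partition`.
#' @param alpha Edge-level and pair-level significance threshold.
#' @param permutations Number of score permutations B.
#' @param seed Integer seed.
#' @return The [pair_chi2()] table with `p_perm` and `enriched` columns.
#' @export
enrichment_permutation <- function(edges, behavior, partition, alpha = 0.05,
                                   permutations = 1000, seed = 1L) {
  if (permutations < 1) stop("permutations must be >= 1")
  edges <- as.matrix(edges)
  n <- nrow(edges)
  obs_stats <- edge_behavior_correlations(edges, behavior, alpha)
  tab <- pair_chi2(obs_stats, partition)
  ps <- pair_structure(obs_stats$roi_i, obs_stats$roi_j, partition)
  n_edges <- tab$n_edges
  total_edges <- nrow(obs_stats)
  exceed <- integer(nrow(tab))
  perms <- with_seed(seed,
                     replicate(permutations, sample(behavior), simplify = FALSE))
  t_obs <- ifelse(tab$over_expected, tab$chi2, -tab$chi2)
  for (p in perms) {
    sig <- edge_cor_p(edge_cor(edges, p), n) < alpha
    obs_p <- tabulate(ps$pair_of_edge[sig], nbins = ps$n_pairs)
    chi_p <- pair_chi2_values(n_edges, obs_p, total_edges, sum(sig))
    exp_p <- sum(sig) * n_edges / total_edges
    t_p <- ifelse(obs_p > exp_p, chi_p, -chi_p)
    exceed <- exceed + (t_p >= t_obs)
  }
  tab$p_perm <- (1 + exceed) / (permutations + 1)
  tab$enriched <- tab$over_expected & tab$p_perm < alpha
  tab
}
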