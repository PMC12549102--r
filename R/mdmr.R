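#' Manhattan distance matrix between subjects
#'
#' `d[a, b] = sum_f |profile_a[f] - profile_b[f]|`, the L1 metric over
#' connectivity features (z units).
#'
#' @param profiles subject x feature numeric matrix.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
manhattan_distances <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 subjects")
  if (anyNA(profiles)) stop("profiles contain missing values")
  as.matrix(stats::dist(profiles, method = "manhattan"))
}

#' Gower-centered inner-product matrix
#'
#' `G = -1/2 * C (d o d) C` with `C = I - 11'/n`: the doubly centered matrix
#' of squared distances, whose trace is the total sum of squares about the
#' multivariate centroid. Every row and column of G sums to zero.
#'
#' @param d Symmetric distance matrix.
#' @return Symmetric centered matrix G of the same dimension.
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  g <- a - outer(rm_, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) + mean(a)
  (g + t(g)) / 2
}

#' Build an MDMR design matrix
#'
#' Intercept plus the named covariate columns, checked for full column rank.
#'
#' @param covariates data.frame of per-scan covariates.
#' @param columns Covariate names to include, in order.
#' @return Numeric matrix with an `intercept` column first.
#' @export
build_design <- function(covariates, columns) {
  missing_cols <- setdiff(columns, names(covariates))
  if (length(missing_cols))
    stop("covariates missing: ", paste(missing_cols, collapse = ", "))
  x <- cbind(intercept = 1,
             as.matrix(covariates[, columns, drop = FALSE]))
  if (anyNA(x)) stop("design matrix contains missing values")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  x
}

# Hat matrix of a design via its QR decomposition.
hat_matrix <- function(x) {
  q <- qr.Q(qr(x))
  tcrossprod(q)
}

# tr(A %*% G) for symmetric A, G without forming the product.
tr_prod <- function(a, g) sum(a * g)

#' Multivariate distance matrix regression
#'
#' Tests how the design's covariates account for inter-subject distances.
#' The omnibus pseudo-F compares the variation captured by the full design
#' against the residual variation of the Gower-centered matrix G:
#' `F = [tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)]` with H the hat matrix and
#' m the number of non-intercept columns; pseudo-R2 is `tr(HGH)/tr(G)`.
#' Omnibus significance permutes subject labels of G directly; per-factor
#' (conditional) tests compare the full design against the design without
#' that factor under the Freedman-Lane scheme, permuting reduced-model
#' residual structure so nuisance covariates are held fixed. Permutation p
#' values use the `(b + 1) / (B + 1)` estimator and so never reach zero.
#'
#' @param d Subject distance matrix (or `dist`).
#' @param x Design matrix from [build_design()] (intercept first).
#' @param factors Non-intercept column names to test conditionally; defaults
#'   to all of them.
#' @param permutations Number of permutations B.
#' @param seed Integer seed for the permutation draw.
#' @return data.frame with one row per factor plus an `omnibus` row:
#'   columns `factor`, `df`, `pseudo_f`, `pseudo_r2`, `p_perm`, `n_perm`.
#' @export
mdmr_fit <- function(d, x, factors = NULL, permutations = 999, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  x <- as.matrix(x)
  if (nrow(x) != n) stop("design rows must align with the distance matrix")
  if (permutations < 1) stop("permutations must be >= 1")
  cn <- colnames(x)
  if (is.null(cn) || cn[1] != "intercept")
    stop("design must carry an intercept column first")
  if (is.null(factors)) factors <- cn[-1]
  if (!all(factors %in% cn[-1])) stop("factors must be non-intercept design columns")
  m <- ncol(x) - 1L
  df_res <- n - m - 1L
  if (df_res < 1) stop("design has no residual degrees of freedom")

  g <- gower_center(d)
  h <- hat_matrix(x)
  trg <- tr_prod(diag(n), g)
  ss_model <- tr_prod(h, g)
  ss_res <- trg - ss_model
  f_omni <- (ss_model / m) / (ss_res / df_res)
  r2_omni <- ss_model / trg

  perms <- with_seed(seed, replicate(permutations, sample.int(n), simplify = FALSE))

  # omnibus: raw relabeling of subjects in G
  f_omni_perm <- vapply(perms, function(p) {
    gp <- g[p, p]
    ssm <- tr_prod(h, gp)
    (ssm / m) / ((trg - ssm) / df_res)
  }, numeric(1))
  p_omni <- (1 + sum(f_omni_perm >= f_omni)) / (permutations + 1)

  out <- data.frame(factor = "omnibus", df = m, pseudo_f = f_omni,
                    pseudo_r2 = r2_omni, p_perm = p_omni,
                    n_perm = permutations, stringsAsFactors = FALSE)

  for (fc in factors) {
    keep <- setdiff(cn, fc)
    h_red <- hat_matrix(x[, keep, drop = FALSE])
    h_diff <- h - h_red
    df_f <- 1L
    ss_f <- tr_prod(h_diff, g)
    f_obs <- (ss_f / df_f) / (ss_res / df_res)
    r_red <- diag(n) - h_red
    f_perm <- vapply(perms, function(p) {
      mp <- h_red + r_red[p, , drop = FALSE]
      gp <- mp %*% g %*% t(mp)
      ssf <- tr_prod(h_diff, gp)
      ssr <- tr_prod(diag(n), gp) - tr_prod(h, gp)
      (ssf / df_f) / (ssr / df_res)
    }, numeric(1))
    p_f <- (1 + sum(f_perm >= f_obs)) / (permutations + 1)
    out <- rbind(out, data.frame(factor = fc, df = df_f, pseudo_f = f_obs,
                                 pseudo_r2 = ss_f / trg, p_perm = p_f,
                                 n_perm = permutations,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Marginal covariate screening
#'
#' Optional model selection: each candidate covariate is tested alone
#' (marginal omnibus MDMR) and retained when its permutation p falls below
#' `keep_threshold`.
#'
#' @param d Subject distance matrix.
#' @param covariates Covariate data.frame.
#' @param candidates Covariate names to screen.
#' @param keep_threshold Retention threshold on the marginal p value.
#' @param permutations,seed Permutation settings.
#' @return data.frame with `covariate`, `pseudo_f`, `pseudo_r2`, `p_perm`,
#'   `keep`.
#' @export
screen_covariates <- function(d, covariates, candidates, keep_threshold = 0.10,
                              permutations = 999, seed = 1L) {
  seeds <- split_seed(seed, length(candidates))
  rows <- lapply(seq_along(candidates), function(k) {
    x <- build_design(covariates, candidates[k])
    res <- mdmr_fit(d, x, factors = character(0), permutations = permutations,
                    seed = seeds[k])
    data.frame(covariate = candidates[k], pseudo_f = res$pseudo_f[1],
               pseudo_r2 = res$pseudo_r2[1], p_perm = res$p_perm[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$keep <- out$p_perm < keep_threshold
  out
}

#' Connectome-wide association scan
#'
#' Runs [mdmr_fit()] either once on Manhattan distances over the full edge
#' vector (`whole_connectome`) or per ROI on that ROI's connectivity profile
#' (the n-1 edges incident to it), yielding one result table per unit.
#'
#' @param edges subject x edge matrix from [edge_matrix()] (canonical edge
#'   ordering, columns named `roi_i|roi_j`).
#' @param x Design matrix from [build_design()].
#' @param mode `"whole_connectome"` or `"per_roi"`.
#' @param factors Factors to test (see [mdmr_fit()]).
#' @param permutations,seed Permutation settings.
#' @param labels ROI labels; inferred from the edge count if NULL.
#' @return data.frame of MDMR results with a `unit` column (ROI name or
#'   "whole_connectome").
#' @export
cwas_scan <- function(edges, x, mode = c("whole_connectome", "per_roi"),
                      factors = NULL, permutations = 999, seed = 1L,
                      labels = NULL) {
  mode <- match.arg(mode)
  edges <- as.matrix(edges)
  if (nrow(edges) < 2) stop("need at least 2 subjects")
  if (is.null(labels)) {
    n <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
    if (n != round(n)) stop("edge count is not C(n, 2) for integer n")
    labels <- roi_labels(as.integer(n))
  }
  if (mode == "whole_connectome") {
    res <- mdmr_fit(manhattan_distances(edges), x, factors, permutations, seed)
    return(cbind(unit = "whole_connectome", res))
  }
  idx <- edge_index(labels)
  seeds <- split_seed(seed, length(labels))
  out <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    cols <- which(idx$i == k | idx$j == k)
    res <- mdmr_fit(manhattan_distances(edges[, cols, drop = FALSE]),
                    x, factors, permutations, seeds[k])
    out[[k]] <- cbind(unit = labels[k], res)
  }
  do.call(rbind, out)
}
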