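#' Pearson connectivity matrix
#'
#' Pairwise Pearson correlation of ROI time series over retained volumes.
#'
#' @param timeseries ROI x volume matrix.
#' @param mask Optional logical keep mask over volumes.
#' @return Symmetric ROI x ROI correlation matrix with unit diagonal.
#' @export
pearson_connectome <- function(timeseries, mask = NULL) {
  timeseries <- as.matrix(timeseries)
  if (!is.null(mask)) {
    if (length(mask) != ncol(timeseries)) stop("mask length must match volumes")
    timeseries <- timeseries[, mask, drop = FALSE]
  }
  if (ncol(timeseries) < 3) stop("need at least 3 retained volumes")
  sds <- apply(timeseries, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(timeseries)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant ROI series: ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(timeseries))
  (r + t(r)) / 2
}

#' Fisher z transform
#'
#' `atanh(r)` after clipping `|r|` to `1 - 1e-7`, so perfect correlations map
#' to a large finite z rather than infinity. Strictly increasing and odd.
#'
#' @param r Correlations, any numeric shape; must satisfy `|r| <= 1`.
#' @return z values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Build a connectome from a scan
#'
#' Pearson correlation over retained volumes, Fisher z transformed.
#'
#' @param scan A [subject_scan()].
#' @return List of class `connectome` with `scan_id`, `z_matrix` (zero
#'   diagonal) and `roi_labels`.
#' @export
build_connectome <- function(scan) {
  r <- pearson_connectome(scan$timeseries, scan$keep_mask)
  z <- fisher_z(r)
  diag(z) <- 0
  labs <- rownames(scan$timeseries)
  if (is.null(labs)) labs <- roi_labels(nrow(scan$timeseries))
  dimnames(z) <- list(labs, labs)
  structure(list(scan_id = scan$scan_id, z_matrix = z, roi_labels = labs),
            class = "connectome")
}

#' Vectorize the upper triangle of a connectome
#'
#' Canonical row-major upper-triangle ordering (see [edge_index()]);
#' invertible by [devectorize_edges()].
#'
#' @param m Symmetric matrix, or a `connectome`.
#' @return Numeric vector of length C(n, 2), named `roi_i|roi_j`.
#' @export
vectorize_edges <- function(m) {
  if (inherits(m, "connectome")) m <- m$z_matrix
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-10) stop("matrix is not symmetric")
  labs <- rownames(m)
  if (is.null(labs)) labs <- roi_labels(nrow(m))
  idx <- edge_index(labs)
  v <- m[cbind(idx$i, idx$j)]
  names(v) <- paste(idx$roi_i, idx$roi_j, sep = "|")
  v
}

#' @rdname vectorize_edges
#' @param v Edge vector in canonical order.
#' @param labels ROI labels (defines n); inferred from `length(v)` if NULL.
#' @export
devectorize_edges <- function(v, labels = NULL) {
  if (is.null(labels)) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (n != round(n)) stop("vector length is not C(n, 2) for integer n")
    labels <- roi_labels(as.integer(n))
  }
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  idx <- edge_index(labels)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}

#' Connectivity profile of one ROI
#'
#' The n-1 z values linking `roi` to every other ROI, in canonical label
#' order.
#'
#' @param connectome A `connectome`.
#' @param roi ROI label.
#' @return Named numeric vector of length n_rois - 1.
#' @export
roi_profile <- function(connectome, roi) {
  labs <- connectome$roi_labels
  k <- match(roi, labs)
  if (is.na(k)) stop("unknown ROI label: ", roi)
  p <- connectome$z_matrix[k, -k]
  names(p) <- labs[-k]
  p
}

#' Stack cohort edge vectors
#'
#' @param connectomes List of `connectome` objects sharing one ROI set.
#' @return subject x edge matrix, rows named by scan id.
#' @export
edge_matrix <- function(connectomes) {
  labs <- connectomes[[1]]$roi_labels
  for (cn in connectomes)
    if (!identical(cn$roi_labels, labs)) stop("inconsistent ROI sets")
  m <- t(vapply(connectomes, vectorize_edges,
                numeric(length(labs) * (length(labs) - 1) / 2)))
  rownames(m) <- vapply(connectomes, function(cn) cn$scan_id, character(1))
  m
}
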