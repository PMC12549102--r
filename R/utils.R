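#' Canonical edge ordering for an ROI set
#'
#' Edges are enumerated row-major over the upper triangle: (1,2), (1,3), ...,
#' (1,n), (2,3), ... so that every module agrees on which vector element is
#' which ROI pair. ROI order is taken from the label vector as given.
#'
#' @param roi_labels Character vector of ROI labels (length n).
#' @return A data.frame with columns `i`, `j` (integer indices, i < j),
#'   `roi_i`, `roi_j` (labels), one row per unordered pair, C(n,2) rows.
#' @export
edge_index <- function(roi_labels) {
  n <- length(roi_labels)
  if (n < 2) stop("need at least 2 ROIs to enumerate edges")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j,
             roi_i = roi_labels[i], roi_j = roi_labels[j],
             stringsAsFactors = FALSE)
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps` and the
#' matrix is reassembled, then rescaled to unit diagonal when the input was a
#' correlation matrix. Deterministic.
#'
#' @param m Symmetric matrix.
#' @param eps Smallest admissible eigenvalue.
#' @param correlation If TRUE, restore a unit diagonal after clipping.
#' @return Positive-definite symmetric matrix.
#' @keywords internal
near_pd <- function(m, eps = 1e-8, correlation = TRUE) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  if (correlation) {
    d <- sqrt(diag(out))
    if (any(d <= 0)) stop("correlation matrix not repairable to positive-definite")
    out <- out / tcrossprod(d)
    diag(out) <- 1
  }
  out
}

# Derive per-stage child seeds from one master seed, reproducibly and
# independently of the caller's RNG state.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}
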