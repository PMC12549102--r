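#' Group-average connectome
#'
#' Element-wise mean of subject z matrices.
#'
#' @param connectomes List of `connectome` objects on one ROI set.
#' @return Symmetric group-mean z matrix.
#' @export
group_connectome <- function(connectomes) {
  if (!length(connectomes)) stop("need at least 1 subject")
  labs <- connectomes[[1]]$roi_labels
  acc <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (cn in connectomes) {
    if (!identical(cn$roi_labels, labs)) stop("inconsistent ROI sets")
    acc <- acc + cn$z_matrix
  }
  acc / length(connectomes)
}

# Signed modularity matrix with the asymmetric positive/negative convention:
# positive weights contribute at full strength (normalized by total positive
# strength v+), negative weights are down-weighted by v+ + v-, so positive
# structure dominates the partition. gamma is the resolution parameter.
signed_modularity_matrix <- function(w, gamma) {
  w <- as.matrix(w)
  diag(w) <- 0
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  sp <- rowSums(wp); vp <- sum(sp)
  sn <- rowSums(wn); vn <- sum(sn)
  m <- matrix(0, nrow(w), ncol(w))
  if (vp > 0) m <- m + (wp - gamma * tcrossprod(sp) / vp) / vp
  if (vn > 0) m <- m - (wn - gamma * tcrossprod(sn) / vn) / (vp + vn)
  diag(m) <- 0
  (m + t(m)) / 2
}

relabel_contiguous <- function(comm) {
  match(comm, unique(comm))
}

# Multi-level (Louvain-style) optimization over an arbitrary symmetric
# modularity matrix: greedy local node moves on the aggregated matrix,
# community aggregation, repeated until the partition stops changing.
louvain_full <- function(m, seed) {
  n <- nrow(m)
  comm <- seq_len(n)
  step_seed <- seed
  repeat {
    # local moving on the aggregated matrix
    ids <- sort(unique(comm))
    s <- matrix(0, n, length(ids))
    s[cbind(seq_len(n), match(comm, ids))] <- 1
    magg <- t(s) %*% m %*% s
    diag(magg) <- 0
    sub <- move_nodes(magg, step_seed)
    step_seed <- step_seed + 1000L
    new_comm <- sub[match(comm, ids)]
    if (length(unique(new_comm)) == length(ids)) break
    comm <- new_comm
  }
  relabel_contiguous(comm)
}

# Greedy local node moving until convergence; returns community labels.
move_nodes <- function(m, seed) {
  n <- nrow(m)
  comm <- seq_len(n)
  if (n == 1) return(comm)
  ord <- with_seed(seed, sample.int(n))
  repeat {
    moved <- FALSE
    for (i in ord) {
      aff <- tapply(m[i, -i], comm[-i], sum)
      cur <- aff[as.character(comm[i])]
      if (is.na(cur)) cur <- 0  # singleton community
      best <- which.max(aff)
      if (length(best) && aff[[best]] > cur + 1e-12) {
        comm[i] <- as.integer(names(aff)[best])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  relabel_contiguous(comm)
}

#' Detect modules by signed-modularity consensus clustering
#'
#' Louvain-style greedy maximization of signed modularity at resolution
#' `resolution`, with negative weights entering under the asymmetric
#' convention (positive weights dominate). The partition is stabilized by
#' consensus clustering: `consensus_runs` seeded restarts vote through a
#' co-assignment matrix, which is thresholded at 0.5 and re-clustered until
#' all restarts agree.
#'
#' @param w Symmetric weight matrix (group-mean z values; diagonal ignored).
#' @param resolution Resolution gamma; larger values favor smaller modules
#'   (default 1.5, tuned toward finer partitions).
#' @param seed Master seed; the consensus is deterministic given it.
#' @param consensus_runs Number of restarts per consensus round.
#' @return List of class `module_partition` with `assignment` (named integer
#'   vector, module ids contiguous from 1), `n_modules`, `resolution`,
#'   `modularity_q` and `seed`.
#' @export
detect_modules <- function(w, resolution = 1.5, seed = 1L, consensus_runs = 100) {
  w <- as.matrix(w)
  if (!nrow(w)) stop("empty graph")
  if (max(abs(w - t(w))) > 1e-8) stop("weight matrix must be symmetric")
  labs <- rownames(w)
  if (is.null(labs)) labs <- roi_labels(nrow(w))
  m <- signed_modularity_matrix(w, resolution)
  seeds <- split_seed(seed, consensus_runs)
  parts <- lapply(seeds, function(s) louvain_full(m, s))
  for (round in seq_len(20)) {
    if (all_identical_partitions(parts)) break
    co <- Reduce(`+`, lapply(parts, function(p) outer(p, p, "==") * 1)) /
      length(parts)
    co[co < 0.5] <- 0
    diag(co) <- 0
    mcons <- signed_modularity_matrix(co, 1)
    parts <- lapply(seeds, function(s) louvain_full(mcons, s))
  }
  assignment <- canonical_partition(parts[[1]])
  names(assignment) <- labs
  q <- sum(m[outer(assignment, assignment, "==")])
  structure(list(assignment = assignment,
                 n_modules = length(unique(assignment)),
                 resolution = resolution, modularity_q = q,
                 seed = as.integer(seed)),
            class = "module_partition")
}

all_identical_partitions <- function(parts) {
  ref <- canonical_partition(parts[[1]])
  all(vapply(parts, function(p) identical(canonical_partition(p), ref),
             logical(1)))
}

canonical_partition <- function(p) {
  as.integer(match(p, unique(p)))
}
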