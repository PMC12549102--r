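# Shared builders for the test suite. Everything is generated in code; no
# fixture files.

# A module_partition with planted contiguous blocks, bypassing detection.
make_partition <- function(n_rois, n_modules) {
  structure(list(assignment = stats::setNames(planted_modules(n_rois, n_modules),
                                              roi_labels(n_rois)),
                 n_modules = as.integer(n_modules),
                 resolution = NA_real_, modularity_q = NA_real_, seed = NA_integer_),
            class = "module_partition")
}

# A quiet scan: deterministic sinusoidal ROI series, zero motion.
make_scan <- function(n_rois = 4, n_volumes = 20, tr = 3) {
  ts <- outer(seq_len(n_rois), seq_len(n_volumes),
              function(i, t) sin(t / i) + 0.1 * i * t)
  rownames(ts) <- roi_labels(n_rois)
  subject_scan("scanA", ts,
               translation_delta = rep(0, n_volumes),
               rotation_delta = rep(0, n_volumes), tr_seconds = tr)
}

# Edge matrix of iid standard-normal "z values" (no structure at all).
random_edges <- function(n_subjects, n_rois, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_subjects * choose(n_rois, 2)), n_subjects)
  idx <- edge_index(roi_labels(n_rois))
  colnames(m) <- paste(idx$roi_i, idx$roi_j, sep = "|")
  m
}

# Simulate a cohort and return its subject x edge matrix plus covariates.
cohort_edges <- function(spec) {
  co <- simulate_cohort(spec)
  list(edges = edge_matrix(lapply(co$subjects, build_connectome)),
       covariates = co$covariates, truth = co$truth)
}
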