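#' Summarize edge-behavior associations
#'
#' Counts of significant edges by direction, with percentages of all tested
#' edges (recomputed from the counts, one-decimal rounding).
#'
#' @param stats EdgeStats table from [edge_behavior_correlations()].
#' @return List with `total_edges`, `total_significant`, `positive`,
#'   `negative`, `pct_positive`, `pct_negative`.
#' @export
summarize_associations <- function(stats) {
  total_edges <- nrow(stats)
  if (!total_edges)
    return(list(total_edges = 0L, total_significant = 0L, positive = 0L,
                negative = 0L, pct_positive = 0, pct_negative = 0))
  pos <- sum(stats$significant & stats$r > 0)
  neg <- sum(stats$significant & stats$r < 0)
  list(total_edges = total_edges, total_significant = pos + neg,
       positive = pos, negative = neg,
       pct_positive = round(100 * pos / total_edges, 1),
       pct_negative = round(100 * neg / total_edges, 1))
}

#' Top associated edges
#'
#' The k strongest positive and k strongest negative edge-behavior
#' correlations, ranked by |r| descending with ties broken by (roi_i, roi_j)
#' label order. Fewer rows are returned when fewer edges of that sign exist.
#'
#' @param stats EdgeStats table.
#' @param k Rows per table.
#' @return List of two data.frames, `positive` and `negative`, each with a
#'   `rank` column.
#' @export
top_edges <- function(stats, k = 10) {
  if (k < 0) stop("k must be >= 0")
  pick <- function(tab) {
    tab <- tab[order(-abs(tab$r), tab$roi_i, tab$roi_j), , drop = FALSE]
    tab <- utils::head(tab, k)
    if (nrow(tab)) tab <- cbind(rank = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
    tab
  }
  list(positive = pick(stats[stats$r > 0, , drop = FALSE]),
       negative = pick(stats[stats$r < 0, , drop = FALSE]))
}

#' Keep one scan per subject
#'
#' Restriction for cohorts with repeated scans: retains the first scan of
#' each subject in table order.
#'
#' @param covariates Covariate table with a `subject_id` column.
#' @return Logical keep vector over rows.
#' @export
one_scan_per_subject <- function(covariates) {
  !duplicated(covariates$subject_id)
}

#' Default pipeline configuration
#'
#' Flat list of every tunable the end-to-end run uses; any entry can be
#' overridden through `run_pipeline(config = list(...))`.
#'
#' MDMR permutations default to 100000 (the protocol value; scale down
#' for exploratory runs), enrichment permutations to 1000.
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(n_subjects = 59, n_rois = 100, n_modules = 14, n_volumes = 110,
       tr_seconds = 3, within_module_r = 0.4, between_module_r = 0.05,
       motion_spike_prob = 0.05,
       trans_thresh_mm = 1.0, rot_thresh_deg = 1.5,
       voxel_frac = 0.10, mad_k = 3.0, min_minutes = 4.0, bandpass = TRUE,
       mdmr_factors = c("retained_volumes", "SSAI", "STAI"),
       mdmr_permutations = 100000, mdmr_mode = "whole_connectome",
       resolution = 1.5, consensus_runs = 100,
       alpha = 0.05, enrichment_permutations = 1000,
       enrichment_behaviors = c("STAI", "SSAI"),
       top_k = 10, seed = 1L)
}

#' Run the full connectome-wide association pipeline
#'
#' simulate -> QC -> connectomes -> MDMR -> modules -> enrichment -> report,
#' writing every table plus a JSON manifest into `out_dir`. All randomness
#' derives from `config$seed`, so identical configs give identical outputs.
#'
#' @param config List overriding entries of [default_config()].
#' @param out_dir Output directory.
#' @param cohort Optional pre-built `cohort` (skips simulation).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("fcwas_run_"),
                         cohort = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stamp <- function(stage) {
    log_lines <<- c(log_lines, sprintf("%s  %s", format(Sys.time()), stage))
  }
  seeds <- split_seed(cfg$seed, 4L)

  stamp("simulate")
  if (is.null(cohort)) {
    spec <- cohort_spec(n_subjects = cfg$n_subjects, n_rois = cfg$n_rois,
                        n_modules = cfg$n_modules, n_volumes = cfg$n_volumes,
                        tr_seconds = cfg$tr_seconds,
                        within_module_r = cfg$within_module_r,
                        between_module_r = cfg$between_module_r,
                        motion_spike_prob = cfg$motion_spike_prob,
                        seed = seeds[1])
    cohort <- simulate_cohort(spec)
  }
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)

  stamp("qc")
  qc <- lapply(cohort$subjects, qc_scan,
               trans_thresh_mm = cfg$trans_thresh_mm,
               rot_thresh_deg = cfg$rot_thresh_deg,
               voxel_frac = cfg$voxel_frac, mad_k = cfg$mad_k,
               min_minutes = cfg$min_minutes, bandpass = cfg$bandpass)
  include <- vapply(qc, `[[`, logical(1), "include")
  qc_tab <- data.frame(
    scan_id = vapply(cohort$subjects, `[[`, character(1), "scan_id"),
    retained_volumes = vapply(qc, function(q) retained_volumes(q$scan), integer(1)),
    include = include)
  utils::write.table(qc_tab, file.path(out_dir, "qc_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scans <- lapply(qc[include], `[[`, "scan")
  covariates <- cohort$covariates[include, , drop = FALSE]
  covariates$retained_volumes <- qc_tab$retained_volumes[include]
  if (length(scans) < 2) stop("cwas stage requires at least 2 included scans")

  stamp("connectome")
  connectomes <- lapply(scans, build_connectome)
  edges <- edge_matrix(connectomes)

  stamp("mdmr")
  x <- build_design(covariates, cfg$mdmr_factors)
  mdmr <- cwas_scan(edges, x, mode = cfg$mdmr_mode,
                    permutations = cfg$mdmr_permutations, seed = seeds[2],
                    labels = connectomes[[1]]$roi_labels)
  utils::write.table(mdmr, file.path(out_dir, "mdmr_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stamp("modules")
  w <- group_connectome(connectomes)
  partition <- detect_modules(w, resolution = cfg$resolution, seed = seeds[3],
                              consensus_runs = cfg$consensus_runs)
  utils::write.table(
    data.frame(roi_label = names(partition$assignment),
               module_id = partition$assignment),
    file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  stamp("enrichment")
  enr <- list(); stats <- list(); summaries <- list(); tops <- list()
  e_seeds <- split_seed(seeds[4], max(1L, length(cfg$enrichment_behaviors)))
  for (q in seq_along(cfg$enrichment_behaviors)) {
    b <- cfg$enrichment_behaviors[q]
    st <- edge_behavior_correlations(edges, covariates[[b]], cfg$alpha)
    stats[[b]] <- st
    utils::write.csv(st, file.path(out_dir, sprintf("edge_stats_%s.csv", b)),
                     row.names = FALSE)
    enr[[b]] <- enrichment_permutation(edges, covariates[[b]], partition,
                                       alpha = cfg$alpha,
                                       permutations = cfg$enrichment_permutations,
                                       seed = e_seeds[q])
    utils::write.table(enr[[b]],
                       file.path(out_dir, sprintf("enrichment_%s.tsv", b)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[b]] <- summarize_associations(st)
    tops[[b]] <- top_edges(st, cfg$top_k)
  }

  stamp("report")
  manifest <- list(package = "fcwas",
                   version = as.character(utils::packageVersion("fcwas")),
                   r_version = R.version.string,
                   seed = cfg$seed, stage_seeds = seeds, config = cfg,
                   n_scans_simulated = length(cohort$subjects),
                   n_scans_included = sum(include))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summaries, file.path(out_dir, "association_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(config = cfg, cohort = cohort, qc = qc_tab,
                 covariates = covariates, edges = edges, mdmr = mdmr,
                 partition = partition, enrichment = enr,
                 edge_stats = stats, summaries = summaries, top_edges = tops,
                 out_dir = out_dir))
}
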