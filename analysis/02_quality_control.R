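#!/usr/bin/env Rscript
# Stage 2 — motion censoring and scan inclusion.
#
# Applies the censoring rules to every scan: frame-to-frame translation
# > 1 mm or rotation > 1.5 degrees censors the volume and its predecessor;
# volumes where > 10% of ROI signals deviate > 3 scaled MADs from their
# series median are dropped; scans keep >= 4 minutes of data or are
# excluded. Included scans are band-passed (0.009-0.08 Hz) and residualized
# against motion regressors. Writes per-scan QC decisions and the cleaned
# series.

library(fcwas)

cohort <- read_cohort("results/cohort", tr_seconds = 3)
qc <- lapply(cohort$subjects, qc_scan)
include <- vapply(qc, `[[`, logical(1), "include")
tab <- data.frame(
  scan_id = vapply(cohort$subjects, `[[`, character(1), "scan_id"),
  raw_volumes = vapply(cohort$subjects, function(s) ncol(s$timeseries), integer(1)),
  retained_volumes = vapply(qc, function(q) retained_volumes(q$scan), integer(1)),
  minutes = vapply(qc, function(q) retained_volumes(q$scan) * q$scan$tr_seconds / 60,
                   numeric(1)),
  include = include)
dir.create("results/clean", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/qc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (q in qc[include])
  write.table(q$scan$timeseries,
              file.path("results/clean", paste0(q$scan$scan_id, "_clean.tsv")),
              sep = "\t", quote = FALSE, col.names = FALSE)

cat(sprintf("included %d of %d scans; retained volumes mean (SD): %.1f (%.1f)\n",
            sum(include), length(include),
            mean(tab$retained_volumes[include]),
            sd(tab$retained_volumes[include])))
cat("wrote results/qc_summary.tsv and results/clean/\n")
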