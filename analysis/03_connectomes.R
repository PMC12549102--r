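#!/usr/bin/env Rscript
# Stage 3 — subject connectomes.
#
# Pearson correlation of the cleaned ROI series per scan, Fisher z
# transformed, vectorized over the 4950 canonical edges. Writes the
# subject x edge matrix and the group-average connectome.

library(fcwas)

cohort <- read_cohort("results/cohort", tr_seconds = 3)
qc_tab <- read.table("results/qc_summary.tsv", header = TRUE, sep = "\t")
keep <- qc_tab$include
clean <- lapply(qc_tab$scan_id[keep], function(id) {
  ts <- as.matrix(read.table(file.path("results/clean", paste0(id, "_clean.tsv")),
                             sep = "\t", row.names = 1))
  colnames(ts) <- NULL
  subject_scan(id, ts, rep(0, ncol(ts)), rep(0, ncol(ts)), 3)
})
connectomes <- lapply(clean, build_connectome)
edges <- edge_matrix(connectomes)
w <- group_connectome(connectomes)

write.csv(edges, "results/edge_matrix.csv")
write.csv(w, "results/group_connectome.csv")
cov <- cohort$covariates[keep, , drop = FALSE]
cov$retained_volumes <- qc_tab$retained_volumes[keep]
write.csv(cov, "results/covariates_included.csv", row.names = FALSE)

cat(sprintf("built %d connectomes; %d edges per subject\n",
            nrow(edges), ncol(edges)))
cat(sprintf("group-mean |z|: %.3f (within-range check: max %.3f)\n",
            mean(abs(w[upper.tri(w)])), max(abs(w))))
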