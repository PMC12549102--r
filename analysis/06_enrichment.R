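#!/usr/bin/env Rscript
# Stage 6 — edge-behavior screening and network-pair enrichment.
#
# Pearson correlation of each of the 4950 edges with the STAI and SSAI
# scores (two-tailed p < .05 marks an edge significant), then the 1-df
# chi-square enrichment of significant edges within each module pair,
# referred to a null built from 1000 permutations of the behavior score.

library(fcwas)

seed <- 20260925L
edges <- as.matrix(read.csv("results/edge_matrix.csv", row.names = 1))
cov <- read.csv("results/covariates_included.csv")
mods <- read.table("results/modules.tsv", header = TRUE, sep = "\t")
part <- structure(list(assignment = setNames(mods$module_id, mods$roi_label),
                       n_modules = max(mods$module_id)),
                  class = "module_partition")

for (beh in c("STAI", "SSAI")) {
  st <- edge_behavior_correlations(edges, cov[[beh]], alpha = 0.05)
  write.csv(st, sprintf("results/edge_stats_%s.csv", beh), row.names = FALSE)
  sm <- summarize_associations(st)
  cat(sprintf("%s: %d significant edges (%d pos = %.1f%%, %d neg = %.1f%%)\n",
              beh, sm$total_significant, sm$positive, sm$pct_positive,
              sm$negative, sm$pct_negative))
  enr <- enrichment_permutation(edges, cov[[beh]], part, alpha = 0.05,
                                permutations = 1000, seed = seed)
  seed <- seed + 1L
  write.table(enr, sprintf("results/enrichment_%s.tsv", beh), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hit <- enr[enr$enriched, ]
  cat(sprintf("%s: %d of %d network pairs enriched\n", beh, nrow(hit), nrow(enr)))
  if (nrow(hit)) print(hit[order(hit$p_perm), ], digits = 3)
}
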