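#!/usr/bin/env Rscript
# Stage 7 — report tables.
#
# Top-10 positive and negative edge-behavior correlations per instrument
# and a run summary pulling the MDMR, module and enrichment results
# together.

library(fcwas)

summary <- list()
for (beh in c("STAI", "SSAI")) {
  st <- read.csv(sprintf("results/edge_stats_%s.csv", beh))
  tops <- top_edges(st, k = 10)
  write.table(tops$positive, sprintf("results/top10_positive_%s.tsv", beh),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tops$negative, sprintf("results/top10_negative_%s.tsv", beh),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary[[beh]] <- summarize_associations(st)
  cat(sprintf("\n%s top positive edges:\n", beh))
  print(tops$positive[, c("rank", "roi_i", "roi_j", "r", "p")], digits = 2)
}
mdmr <- read.table("results/mdmr_results.tsv", header = TRUE, sep = "\t")
mods <- read.table("results/modules.tsv", header = TRUE, sep = "\t")
summary$mdmr <- mdmr[, c("factor", "pseudo_f", "pseudo_r2", "p_perm")]
summary$n_modules <- max(mods$module_id)
jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("\nwrote results/summary.json\n")
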