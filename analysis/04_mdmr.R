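#!/usr/bin/env Rscript
# Stage 4 — multivariate distance matrix regression.
#
# Manhattan distances between subjects' edge vectors, marginal covariate
# screening (keep threshold 0.10), then the whole-connectome MDMR with
# Freedman-Lane permutation inference on the retained factors. Permutations
# are set to 9999 here; the method default is 100000 and is purely a
# precision choice for the p values.

library(fcwas)

seed <- 20260923L
edges <- as.matrix(read.csv("results/edge_matrix.csv", row.names = 1))
cov <- read.csv("results/covariates_included.csv")

d <- manhattan_distances(edges)
candidates <- c("retained_volumes", "SSAI", "STAI", "PSS", "EPDS")
screen <- screen_covariates(d, cov, candidates, keep_threshold = 0.10,
                            permutations = 999, seed = seed)
write.table(screen, "results/covariate_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("marginal screening:\n"); print(screen, digits = 3)

# retained_volumes always stays in as the nuisance covariate; screened-in
# behaviors are tested conditionally
factors <- union("retained_volumes", screen$covariate[screen$keep])
x <- build_design(cov, factors)
res <- cwas_scan(edges, x, mode = "whole_connectome", permutations = 9999,
                 seed = seed + 1L)
write.table(res, "results/mdmr_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwhole-connectome MDMR:\n")
print(res[, c("factor", "pseudo_f", "pseudo_r2", "p_perm")], digits = 3)
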