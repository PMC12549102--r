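#!/usr/bin/env Rscript
# Stage 1 — synthetic cohort.
#
# Builds the study-scale synthetic cohort: 59 scans, 100 ROIs in 14 planted
# modules, 110 volumes at TR 3 s, questionnaire scores at the instruments'
# cohort moments, occasional motion spikes, and a ground-truth behavior
# effect: the 49 edges joining planted modules 1 and 2 gain 0.01 correlation
# units per STAI point (pilot-calibrated so the enrichment stage has a real
# signal to find). Writes the cohort as plain text under results/cohort/.

library(fcwas)

seed <- 20260922L
out <- "results/cohort"

eff <- effect_spec("STAI", as.matrix(expand.grid(1:7, 8:14)),
                   slope_per_unit = 0.01, base_r = 0.05)
spec <- cohort_spec(effect_specs = list(eff), seed = seed)
cohort <- simulate_cohort(spec)
write_cohort(cohort, out)

cat(sprintf("simulated %d scans x %d ROIs x %d volumes (TR %g s)\n",
            spec$n_subjects, spec$n_rois, spec$n_volumes, spec$tr_seconds))
cat(sprintf("planted: %d modules; STAI effect on %d edges (slope %.3f/unit)\n",
            spec$n_modules, nrow(eff$edges), eff$slope_per_unit))
print(round(sapply(cohort$covariates[c("SSAI", "STAI", "PSS", "EPDS")],
                   function(x) c(mean = mean(x), sd = sd(x))), 2))
cat("wrote", out, "\n")
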