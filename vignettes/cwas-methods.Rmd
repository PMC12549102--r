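---
title: "Methods: distance-based connectome-wide association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based connectome-wide association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `fcwas`, the tunable
parameters and their defaults, the synthetic cohort the tests run on, and
the numerical and design choices that were genuinely open.

## The analysis model

The workflow asks whether a behavioral covariate accounts for
inter-subject differences in resting-state functional connectivity, in a
cohort regime typical of fetal imaging: few subjects (tens), short scans
(minutes), heavy motion, and small effect sizes.

1. **Connectomes.** For each scan, connectivity is the Pearson correlation
   of ROI time series over retained volumes, Fisher z transformed. The
   C(n,2) upper-triangle values (row-major, keyed by ROI label order) form
   the subject's edge vector; all modules share this canonical ordering.
2. **Distances.** Subjects are compared by the Manhattan (L1) distance
   between edge vectors. L1 is preferred over L2 in this high-dimensional,
   heavy-tailed setting because no single aberrant edge can dominate the
   distance quadratically.
3. **MDMR.** With the Gower-centered matrix G = −½C(D∘D)C and hat matrix H
   of the design, pseudo-F = [tr(HGH)/m]/[tr((I−H)G(I−H))/(n−m−1)] and
   pseudo-R² = tr(HGH)/tr(G). When distances are Euclidean on a univariate
   response, tr(HGH) and tr((I−H)G(I−H)) are exactly the regression and
   residual sums of squares, so MDMR collapses to classical OLS F and R².
   The test suite enforces this identity to 1e-8 over random instances;
   `vegan::adonis2` serves as a second, independent cross-check.
4. **Permutation inference.** The omnibus test permutes subject labels of
   G (rows and columns together). Conditional per-factor tests use
   Freedman–Lane: with H_r the hat matrix of the design without the tested
   factor and R_r = I − H_r, each permutation forms
   G* = (H_r + P R_r) G (H_r + P R_r)ᵀ and recomputes the partial F against
   the unpermuted design, so nuisance covariates stay fixed. p = (b+1)/(B+1),
   which can never be zero and keeps the test valid at any B.
5. **Modules.** The group-mean connectome is partitioned by greedy
   multi-level (Louvain-style) maximization of signed modularity. Positive
   and negative weights enter asymmetrically — positive terms normalized by
   the total positive strength v⁺, negative terms down-weighted by
   v⁺ + v⁻ — so correlated structure dominates and weak negative edges
   cannot fragment modules. Consensus clustering stabilizes the partition:
   many seeded restarts vote through a co-assignment matrix, thresholded at
   0.5 and re-clustered until every restart agrees, which makes the result
   a deterministic function of the master seed.
6. **Enrichment.** Every edge is correlated with the behavior score
   (two-tailed t, n−2 df, significant at p < .05 with no edge-level
   multiplicity correction — the screen feeds a second-level test that
   carries the inference). For each of the K(K+1)/2 module pairs
   (within-module pairs included) a 1-df Pearson χ² without continuity
   correction compares in-pair versus out-pair significant-edge counts
   against a uniform spread. Significance comes from permuting the behavior
   score and re-running the whole screen, not just reshuffling counts, so
   the null preserves the correlation structure among edges. The test is
   one-sided (over-representation): the permutation statistic is the signed
   χ² (positive when the pair is over-expected), which makes the call rate
   of truly null pairs match the nominal level — the suite checks ≈5% at
   α = .05 — while pairs with fewer significant edges than expected are
   never called enriched.

## Motion QC rules

* Frame-to-frame translation > 1 mm **or** rotation > 1.5° censors the
  volume *and the preceding one* (the movement began during the preceding
  acquisition). The rotational rule is applied in the same direction as the
  translational one — high motion is censored; both thresholds are
  arguments.
* A volume is dropped when more than 10% of ROI signals deviate from their
  own series median by more than `mad_k` scaled MADs. The deviation
  multiplier is not fixed by the rule itself; the default `mad_k = 3`
  (≈3 robust SDs) is a conventional outlier cut and is exposed as an
  argument. Constant series (MAD 0) never count as deviating, and the
  comparison is strict (exactly 10% keeps the volume).
* Scans keep ≥ 4 minutes of data (80 volumes at TR 3 s) or are excluded.
* Band-pass 0.009–0.08 Hz, order-2 Butterworth, applied forward-backward
  (zero phase) with censored volumes linearly interpolated first and
  re-masked afterwards, so spikes do not ring into retained volumes.
  Whether filtering should precede or follow censoring is not dictated by
  the method; filtering on the interpolated grid before regression is a
  common, defensible order and sits behind the `bandpass` switch.
* Nuisance regression: OLS per ROI on retained volumes against intercept,
  linear trend, the motion traces, their first differences and squares.

## Questionnaires

SSAI/STAI are 20-item instruments scored 20–80, PSS 0–40, EPDS 0–30; out of
range scores are rejected naming the instrument. Symptom flags use the
inclusive cutoffs PSS ≥ 15, EPDS ≥ 10, SSAI/STAI ≥ 40; missing scores give
missing flags rather than `FALSE`, so prevalence summaries are not biased
low. Flagging is monotone by construction and the suite checks it over the
full score grids.

## The synthetic cohort

The generator's defaults are the study conditions the workflow targets: 59
scans, 100 ROIs in 14 equal modules (remainder ROIs to the last), 110
volumes at TR 3 s, within-module correlation 0.4 and between-module 0.05,
and the four instruments at their cohort moments (SSAI 26.66 ± 6.72, STAI
28.09 ± 6.62, PSS 9.27 ± 5.13, EPDS 3.24 ± 2.84, each truncated to its
instrument range).

* **Behavior scores** are truncated normal. The underlying normal
  parameters are moment-matched so the *truncated* distribution has the
  stated mean and SD; truncating N(26.66, 6.72²) at 20 directly would
  inflate the mean by ≈2 points.
* **Time series** are zero-mean multivariate normal draws whose correlation
  matrix carries the block structure; if an effect makes the matrix
  indefinite it is repaired by eigenvalue clipping at 1e-8 followed by
  rescaling to unit diagonal — deterministic, and exact when no repair is
  needed.
* **Planted effects** modulate the *population* correlation of chosen edges
  per subject: target r = base_r + slope·(score − mean score), clipped to
  [−0.9, 0.9]. Because the effect enters the generating correlation rather
  than being mixed in as additive signal, the generating slope is directly
  the quantity a recovery analysis should estimate, and the suite verifies
  recovery within 50% at 500 subjects × 2000 volumes. Effect sizes on the
  r scale are not published for this design; the slope used in recovery
  tests (0.01 r-units per score point, ≈0.07 r-units per behavior SD) was
  fixed once by pilot simulation as the smallest round value that a 59-scan
  cohort detects reliably.
* **Motion traces** keep baseline jitter strictly below the censoring
  thresholds and make Bernoulli spikes strictly exceed them, so every
  volume is unambiguously classifiable and censoring tests are exact. The
  default spike probability 0.05 leaves scans near the observed ~109
  retained volumes.

What the generator does **not** emulate: hemodynamic autocorrelation
(volumes are temporally white), image-space artifacts, spatially varying
noise, site or gestational-age effects, and repeated scans of one subject
(each scan is independent). Passing tests therefore demonstrate the
statistics are implemented and calibrated correctly under the assumed
structure — not that the pipeline is robust to everything real fetal fMRI
contains.

## Numerical choices

* Correlations are clipped to |r| ≤ 1 − 1e-7 before atanh, bounding |z| by
  ≈8.1 while leaving ordinary values untouched.
* Asymmetry beyond 1e-10 in a matrix offered for vectorization is an error,
  not silently symmetrized.
* Louvain moves require a strict gain (> 1e-12) so ties cannot cycle;
  tie-breaks go to the first candidate community in the shuffled order,
  making each restart deterministic given its seed.
* `detect_modules` at γ = 0 merges any positively connected network into
  one module; disconnected positive blocks stay separate at any γ.
* MDMR refuses rank-deficient designs and designs without residual degrees
  of freedom rather than returning unstable statistics.

## Open design decisions

* **Permutation scheme.** Only "permutation testing" is inherent to the
  method; Freedman–Lane was chosen for the conditional tests because it is
  the standard for distance-based tests with nuisance covariates, and raw
  relabeling for the omnibus where there is nothing to condition on.
* **Per-ROI versus whole-connectome MDMR.** Both are provided
  (`cwas_scan(mode=)`); the per-ROI mode tests each ROI's 99-edge profile
  and the whole-connectome mode tests all 4950 edges at once.
* **Covariate selection.** `screen_covariates` retains covariates whose
  marginal omnibus p falls below 0.10 by default; the threshold is an
  argument because no sharper criterion is forced by the method.
* **Repeated scans** are treated as exchangeable units by default;
  `one_scan_per_subject` provides the stricter restriction.
* **Resolution default 1.5**, biased toward smaller modules so that a
  100-ROI network can plausibly resolve ~14 communities; the planted-
  partition suite checks module count is non-decreasing in γ.
* The enrichment null is compared per pair, not pooled across pairs.

## Problem sizes used by the test suite

The suite favors many small replicates over few large ones: MDMR–OLS
equivalence at n = 30 over 100 instances; null calibration on 500 cohorts
of 40 subjects × 30 ROIs at 199 permutations; enrichment calibration on 200
and recovery on 50 cohorts of 59 subjects × 40 ROIs; module recovery at the
full 100 ROIs × 14 modules × 2000 volumes. The full suite runs in a few
minutes on one core.

## Known limitations

* Permutation p values are exchangeability-based; with repeated scans per
  subject the default analysis (like the design it mirrors) treats scans as
  exchangeable, which is anticonservative if within-subject correlation is
  strong — use `one_scan_per_subject` to check sensitivity.
* The MAD-censoring rule operates on ROI-level series; it is a proxy for
  the voxel-level rule it models and its deviation multiplier is a
  convention, not an estimate.
* Signed-modularity Louvain is greedy; consensus removes run-to-run
  variance but not the resolution limit inherent to modularity itself.
* The enrichment χ² treats edges as exchangeable within the screen; edges
  sharing an ROI are correlated, which is exactly why inference relies on
  the permuted-score null rather than the asymptotic χ² reference.
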