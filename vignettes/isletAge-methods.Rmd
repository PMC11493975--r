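---
title: "Models and methods in isletAge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in isletAge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletAge)
```

# The problem

In stable-isotope labelling of mammals (SILAM), an animal is raised on a
¹⁵N-enriched diet until its tissues saturate with label, then switched to a
normal ¹⁴N diet (the *chase*). Genomic DNA synthesised during labelling
carries ¹⁵N; each subsequent cell division replaces half of the nuclear DNA
strands with unlabelled material, so the nuclear ¹⁵N excess halves per
division. Multi-isotope imaging mass spectrometry (MIMS) counts ¹⁵N and ¹⁴N
secondary ions per pixel, which makes the per-nucleus isotope ratio — and
hence each cell's division history — measurable in situ. `isletAge`
implements this birth-dating chain for islet-biology studies of how diet
(ad libitum, calorie restriction, high-fat) changes beta-cell turnover,
together with the companion analyses such studies use: a consensus filter
for stochastic gene-regulatory-network inference, a ROC enrichment screen
for imaging mass-spectrometry ions, and glucose-homeostasis phenotyping
statistics.

Everything is driven by a synthetic-data module with known ground truth, so
the full pipeline is testable without animals or instruments.

# The label-dilution birth-dating model

The core quantity is the *excess atom fraction* `e = f - f_nat`, the
measured ¹⁵N atom fraction minus natural abundance (`f_nat = 0.0037`, the
standard physical constant, exposed as a config value). The dilution law is

```
e(k) = e0 * 0.5^k
```

for `k` divisions since labelling (`label_after_divisions()`), inverted by
`estimate_divisions()` as `k = log2(e_ref / e)`, clipped at zero. Division
counts are computed on excess, not on the raw ratio: the raw ratio stops
halving per division once the natural-abundance background matters.

The initial excess `e0` defaults to diet enrichment minus natural abundance
(0.98 − 0.0037). The actual saturation level a tissue reaches by the end of
labelling is not known here, so this default is a declared stand-in; it is
a constructor argument (`labeling_protocol(initial_excess = ...)`) and every
downstream operation takes the reference excess explicitly.

**Classification.** Post-mitotic reference cells (cortical neurons) define
the cutoff for calling a cell long-lived (LLC). Both reference lines —
mean and minimum neuron ratio — are computed (`reference_thresholds()`);
classification defaults to the *minimum* with an inclusive `>=`, the more
permissive call (a cell as label-retaining as the least-retaining neuron
cannot be distinguished from post-mitotic). The `mean` rule is selectable
via `classify_cells(rule = "mean")`. Nuclei whose measured excess is zero
or negative are noise-dominated: they are counted as young for
classification, excluded from mixture fitting, and flagged `NA` in `k_est`.

**Turnover model.** The generator draws each cell quiescent with
probability `p_q` (no divisions during the chase) or cycling with Poisson
`k ~ Pois(lambda * T)` divisions. The two-component form reproduces the
bimodal per-cell ¹⁵N distributions such studies observe and formalises the
"reserve pool" reading of long-lived cells persisting even under high-fat
diet. The shipped defaults — `p_q` = 0.80/0.55/0.30 and `lambda` =
0.15/0.25/0.40 per month for CR/AL/HFD — were chosen once to reproduce the
reported long-lived fractions (about 80% under CR, about 30% under HFD,
with the ad-libitum group near the up-to-60% baseline known for beta
cells) while keeping the turnover ordering CR < AL < HFD. At a 12-month
chase these give expected LLC fractions of roughly 0.81, 0.57 and 0.33.

**Division-count mixture.** `fit_division_mixture()` deconvolves a cohort's
excess values into division-count classes. On the log2 scale the model is a
finite Gaussian mixture with *fixed* component means `log2(e_ref) - k`,
k = 0..K_max — the dilution law pins the means, so only the weights `w_k`
and a common measurement-noise SD `sigma` are free. EM with fixed means is
monotone in log-likelihood; initialisation is uniform weights and the
sample SD of log2 excess, convergence at a log-likelihood gain below 1e-8,
at most 1000 iterations, with `sigma` floored at 1e-6 to prevent degenerate
collapse. Tests verify the EM against an independent grid maximizer of the
same likelihood.

**Uncertainty.** Cohort LLC fractions carry a cell-level percentile
bootstrap CI (B = 2000 by default); no parametric assumption is made about
the between-cell distribution.

# MIMS quantification

Per-nucleus ratios are computed on *summed* counts over the nucleus mask
(`ratio = sum15/sum14`), never as a mean of per-pixel ratios: per-pixel
ratios are unstable wherever ¹⁴N counts are low, while the pooled-count
ratio is the Poisson-efficient estimator. The same logic applies across
repeated frames: `accumulate_frames()` sums counts channel-wise before any
ratio is taken, and a test confirms the pooled estimator has strictly lower
variance than averaging per-frame ratios.

Segmentation thresholds the ¹⁴N channel with Otsu's method and labels
8-connected components above `min_area_px` (default 50). One physical
caveat is modelled honestly: a nucleus still saturated with ¹⁵N is *dim* on
the ¹⁴N channel (most of its nitrogen is ¹⁵N), so pipelines expecting
label-retaining cells should segment on total nitrogen
(`segment_nuclei(channel = "total")`) or supply external masks, which are
accepted verbatim. Ion-counting corrections (dead time, QSA) are out of
scope — acquisition software applies them upstream.

Registration to electron-microscopy coordinates uses the ³²S fiducials: a
2D affine fit by ordinary least squares (`fit_fiducial_affine()`), refusing
fewer than 3 pairs or collinear geometry, with residual diagnostics
attached. Masks are mapped with nearest-neighbour rounding. Coordinates are
0-based (row, col) pixel sets with centres on integer coordinates.

# Consensus regulatory networks

Stochastic co-expression inference gives different edge lists on every run;
the consensus filter runs inference many times (100 in the modelled
workflow) and retains a TF→target edge only when it appears in at least 80%
of runs (inclusive). Support is the exact rational `appearances / n_runs`,
counted in integer arithmetic; comparisons use a 1e-9 guard so that binary
representation of thresholds like 0.8 cannot flip a boundary case. The
retained edge's importance is averaged over the runs *containing* it; an
`absent_as_zero` option divides by all runs instead, since the merged-join
convention is ambiguous in the field.

Regulon activities are binarized per regulon: activities are clipped into
(0, 1), logit-transformed, and a one- vs two-component Gaussian mixture is
compared by BIC (mclust). Bimodal columns get the posterior crossing point
between the two means as the ON threshold; unimodal or constant columns
fall back to all-OFF — the conservative call, flagged per column. TF
co-activity modules come from Pearson correlation across cells
(pairwise-complete) and average-linkage clustering on `1 - r`;
zero-variance columns are excluded with a warning. Influence ranking uses
betweenness centrality on the directed, unweighted consensus graph
(igraph), with an importance-weighted variant (edge length
`1/mean_importance`) behind a flag; tests verify the unweighted scores
against brute-force path enumeration.

# ROC enrichment screening and mass matching

Each ion image is scored by the probability that a random pixel from one
region outranks a random pixel from the other, computed through the
rank-sum identity `AUC = U / (n_a n_b)` with midranks for ties. Pixels are
the observation units, mirroring imaging-software behaviour. Retention uses
the two-sided inclusive band `|AUC - 0.5| >= 0.1` — two-sided because one
screen reports enrichment in both directions; a one-sided variant is
selectable. Metabolite identification gates on a hard ±0.00565 Da window
(the instrument's ion mass resolution) and reports ppm error diagnostically
rather than filtering on it.

# Phenotyping statistics

* `mtt_auc()`: the pre-bolus sample (−10 min in the modelled assay) is the
  baseline; it is subtracted from all post-bolus points and the excursion
  is integrated trapezoidally over post-bolus timepoints only. The area is
  *net* (signed), so the statistic is invariant to shifting the whole curve.
* `kitt()`: OLS slope of `ln(glucose)` on time over samples in [0, 60]
  minutes, reported as `-slope x 100` %/min (positive for falling glucose),
  with the regression SE.
* `homa_ir()`: fasting glucose (mmol/L) × fasting insulin (mU/L) / 22.5 —
  the conventional divisor, stated explicitly because the source protocol
  names only the inputs.
* `cr_ration()`: steady state at `(1 - restriction)` × mean AL intake
  (default 20% restriction, i.e. feeding 80% of AL consumption), ramped in
  by 0.10 per week to avoid abrupt weight loss.
* `digested_energy()`: intake minus fecal energy, rejecting fecal > intake.
  Energy densities 4.11 (chow) and 5.10 (high-fat) kcal/g ship as named
  defaults for `intake_energy()`.

Units are positional contracts: constructors validate ranges and ordering
(`tolerance_curve()` requires strictly increasing times and positive
glucose), and argument names carry the units (`fasting_glucose_mmol`,
`intake_kcal_per_day`). No runtime unit-algebra system is attempted.

# What the generators emulate — and what they do not

The synthetic module reproduces the *statistical structure* the estimators
face: Poisson ion statistics at realistic doses, intra-nuclear
heterochromatin hotspots (dose ×2 over 15% of the nucleus area, atom
fraction unchanged — DNA-dense pixels emit more ions at the same
enrichment), diet-dependent bimodal division-count distributions,
run-to-run edge instability, bimodal regulon activities, lognormal ion
intensities, and exponential glucose decay with multiplicative noise.
Default rasters are 512×512 pixels with three frames per raster.

They do **not** emulate instrument drift, dead-time/QSA count corrections,
EM image content, cell-shape irregularity (nuclei are disks), spatial
autocorrelation of MALDI pixels within an islet, protein-bound ¹⁵N
turnover, or transcript-level data. Passing tests therefore demonstrate
estimator correctness under the stated noise models, not robustness to
every instrumental artefact of real acquisitions.

# Numerical choices and problem sizes

All generators are pure functions of (parameters, seed), via an isolated
RNG scope that does not disturb the caller's state. Expected-count rasters
are returned alongside sampled ones so expectation-conservation can be
asserted to 1e-9 before sampling. Threshold comparisons at printed
constants (0.8 support, 0.1 AUC deviation, 0.00565 Da) use inclusive
boundaries with a 1e-9 floating-point guard.

The validation suites run at these sizes, chosen as the package's standard
reference experiments: 1000 nuclei across 25 full 512×512 rasters for
ratio-accuracy coverage (each nucleus receives over 1e5 total counts);
2000 cells for mixture-weight recovery (planted weights 0.7/0.3 over
k = 0/3, sigma = 0.1); 500 replicates of 200 cells per diet group for the
LLC-ordering experiment; 100 random digraphs (≤ 8 nodes) for the
betweenness oracle; 1000 replicates at 100 pixels per class for the ROC
null-retention check against the exact Wilcoxon null; 500 replicates for
Kitt recovery at noise SD 0.02, where the ±3 SE band covers the t(6)
fraction 2·pt(3,6)−1 ≈ 0.976 of replicates.

# Known limitations

* The saturation excess `e0` is a protocol declaration, not a measurement;
  absolute division counts shift by `log2` of any mis-specification, while
  LLC classification (neuron-referenced, ratio-based) does not.
* The mixture model assumes a common `sigma` across division classes and
  independence between cells; islet-level clustering is not modelled.
* Betweenness is computed on the unweighted digraph by default; importance
  weighting changes rankings and is available but not the default, since
  the modelled workflow does not state a weighting.
* The ROC screen treats pixels as exchangeable within a region; spatially
  correlated pixels make the effective sample size smaller than the pixel
  count, so instrument-data AUC confidence statements need region-level
  aggregation (`ion_auc` on per-region summaries is available by passing
  region means).
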