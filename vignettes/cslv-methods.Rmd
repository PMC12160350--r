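---
title: "Chromosomal-scale length variation risk scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal-scale length variation risk scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslv)
```

## The quantity being computed

SNP genotyping arrays report, at every probe, a log R ratio (LRR): the log of
the observed probe intensity over the intensity expected for two copies. An
LRR near 0 means two copies at that locus; persistently negative values mean
a deletion, positive values a duplication. Averaging LRR over a chromosome,
or a fixed segment of one, yields a single number that behaves like a
nominal *relative length* of that stretch of genome: a germline deletion
burden shortens it, a duplication burden lengthens it. We call this mean the
chromosomal-scale length variation (CSLV) feature of the segment.

With the 22 autosomes each cut into `k` equal-length pieces, a genome is
summarised by `22*k` numbers — 22 for `k = 1`, 88 for the default `k = 4`.
Sex chromosomes are excluded throughout: their LRR distributions are
confounded by sex, and the feature set is meant to be comparable across all
samples. The dimensionality is small enough that flexible classifiers
(gradient boosting, random forests, stacked ensembles) can be trained on
cohorts of a few hundred cases, which is the practical motivation for the
representation: classical SNP-based polygenic scores need orders of
magnitude more samples than there are informative parameters, while a CSLV
model has fewer than a hundred.

Averaging over thousands of probes also suppresses probe-level noise: for a
segment holding `m` markers, independent per-marker noise of standard
deviation `sigma_marker` contributes only `sigma_marker / sqrt(m)` to the
feature's standard deviation. No masking, winsorising, GC-wave correction
or probe-quality weighting is applied: the feature *is* the plain
arithmetic mean of the non-missing LRR values in the segment, and anything
more is deliberately out of scope for this package.

## Segmentation

A segment map is built from a genome build (chromosome lengths) and a
marker manifest. For a chromosome of length `L` and `k` segments, boundary
`i` sits at `1 + round(i * L / k)`, and segment `i` is the half-open
interval from boundary `i - 1` to boundary `i`. This tiles `[1, L + 1)`
with no gaps or overlaps and keeps segment spans within 1 bp of each other;
a marker at an exact boundary belongs to the right-hand segment. Two
choices here were genuinely open:

* **Equal base-pair span vs equal marker count.** The default is equal bp
  span, because the feature is interpreted as the length of a physical
  chromosome region and should not depend on the probe panel's density
  profile. Equal marker count (`by = "markers"`) is available for users who
  prefer variance-balanced features.
* **Assembly length vs marker span.** Segments are defined on the assembly
  length of each chromosome (GRCh38 autosome lengths ship as the default
  build), not on the first-to-last marker positions, so segment definitions
  are stable across datasets with different panels. The build is a
  stand-in: the original array data never states one, and any build can be
  supplied as a two-column TSV.

A feature is missing for a sample when fewer than `min_markers`
(default 1) non-missing LRR values fall in the segment. On real arrays a
quarter-chromosome holds thousands of probes, so this only matters for toy
fixtures and heavily filtered panels.

## Cohort assembly and evaluation contract

Case/control array cohorts are heavily imbalanced (roughly 10:1 controls to
cases in the motivating data). The package keeps every case and
undersamples controls to a 40:60 case:control mix with age matching:
cases are visited in seed-randomised order, each drawing its quota of
nearest-age unused controls (1 or 2 for the default ratio; ties in age
distance break on the control's sample id). Greedy nearest-age matching was
chosen over optimal bipartite matching because it is linear-time,
deterministic given the seed, and auditable row by row; the matching
quality difference is negligible when controls are plentiful. The matched
cohort is then split 80/20 with label stratification, models are trained
with stratified 5-fold cross-validation on the 80%, and every headline
number is computed on the untouched 20%.

The model zoo is fixed and small — gradient boosting (xgboost), random
forest (ranger), logistic regression, and a stacked ensemble that fits a
logistic combiner to the members' out-of-fold predictions. An automated
model search with a wall-clock budget is intentionally *not* reproduced:
a fixed zoo with a "best mean CV AUC wins" rule gives the same evaluation
contract without a dependency on a proprietary search path. The stack's
combiner is fitted once on the pooled out-of-fold predictions; its per-fold
CV AUCs therefore carry a small optimistic bias relative to a fully nested
scheme, which is acceptable because model selection and reporting rest on
the held-out test set. Missing feature values are imputed with train-set
column medians, stored with the fit and reused at scoring time.

AUC is the Mann-Whitney form (probability a random case outscores a random
control, ties credited one half), computed from midranks, with a percentile
bootstrap confidence interval (2000 resamples) — the reference data do not
state their CI method, so the least parametric common choice was taken.
Run-to-run stability is summarised by repeating the whole
resample/split/fit pipeline five times under shifted seeds and reporting
the mean and sample standard deviation of the test AUCs.

## Quintile stratification and the odds-ratio convention

Test samples are ranked by score (descending, ties broken by sample id) and
cut into five bins; bin 5 holds the highest scores, and when `n` is not a
multiple of five, the larger bins go to the higher quintiles. For quintile
`q` with `a` cases and `b` controls against test-set totals `A` and `B`,
the package computes

    OR_q = (a / b) / (A / B)

— the quintile's odds relative to the *entire test population* — with a
Wald interval on `log(OR)` (`se = sqrt(1/a + 1/b + 1/A + 1/B)`) and a
Haldane–Anscombe +0.5 correction on zero cells. The more common
quintile-vs-complement convention is available via
`reference = "complement"`. The convention is stated explicitly in the
result object because published quintile tables for this method cannot be
reproduced exactly from their own printed counts by either standard
formula; the package ships the published table verbatim as reference data
(`published_quintile_table()`), and the "top quintile nine times the bottom"
headline is the ratio of the published OR column's endpoints (3.47/0.39
≈ 8.9), not a re-derivation. Under the population-reference definition the
control-weighted mean of the five ORs is exactly 1, an algebraic identity
the tests assert to 1e-12.

## Cross-population transfer and feature importance

To probe transferability, a model is trained entirely within one
self-identified group (matching and splitting inside the group), then
evaluated on (i) its own 20% holdout, (ii) each other named group in full,
(iii) "other" — samples in none of the named groups — and (iv) "mixed" —
everything, with the training group represented only by its holdout.
Training samples never appear in any test set. External groups are tested
as-is (not re-matched); whether the original study matched its external
test groups is unstated, and as-is testing is the more conservative
reading.

Feature importance is permutation importance on the held-out test set:
baseline test AUC minus the mean AUC after shuffling one feature column
(10 shuffles by default). It is model-agnostic, unlike SHAP, which is left
as an optional integration rather than a core dependency. The usual caveat
applies and is exercised in the tests: duplicated or strongly correlated
informative features mask one another under permutation.

## The synthetic cohort generator

Because the motivating data are controlled-access, the package bundles a
generator that emulates an array cohort at desk scale with known ground
truth. Marker-level model:

    LRR[s, j] = baseline_s + sum(shifts of CNV events covering marker j) + e_sj

with `baseline_s ~ N(0, sigma_sample)` (an array-level normalisation
offset), `e_sj ~ N(0, sigma_marker)` i.i.d., markers placed uniformly at
random per chromosome, background CNV events Poisson-placed
length-weighted across chromosomes with exponential lengths, and
designated *effect regions* where the event probability differs between
cases and controls (and optionally between groups). Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| `markers_per_chrom` | 500 | desk-scale stand-in for ~82k probes/chromosome |
| `sigma_marker` | 0.15 LRR | typical array probe-level noise |
| `sigma_sample` | 0.02 LRR | small per-array baseline wobble |
| `background_cnv_rate` | 2 events/genome | sparse large-event background |
| `cnv_mean_length` | 10 Mb | events must span multiple sparse markers to be visible |
| deletion / duplication shift | −0.5 / +0.3 | typical array intensity magnitudes |
| age model | cases N(62, 10), controls N(58, 12), floor 18 | onset-age asymmetry so age matching has work to do |

One master seed drives four separate sub-streams (manifest, samples,
events, noise), so the simulated manifest is bit-identical across runs that
differ only in cohort size. Group-specific effect regions are the mechanism
for transfer experiments: shared regions produce transferable models,
disjoint regions produce non-transferable ones.

The generator deliberately omits LD structure, allele frequencies,
genotype calling, GC waves, and probe-quality heterogeneity. Passing tests
on simulated cohorts therefore demonstrate that the *pipeline machinery* is
correct and calibrated — not that any particular AUC is attainable on real
arrays, where those artefacts and much weaker effects dominate.

## Numerical and testing notes

Three subtleties surfaced while validating against closed forms, and are
worth recording:

* **Single-feature AUC ceiling.** For one whole-segment effect present in
  every case and no control, the affected feature is two equal-variance
  Gaussians separated by the event shift, so the best achievable AUC is
  `pnorm(delta / (sd * sqrt(2)))`. This ceiling only binds the *model* when
  `sigma_sample = 0`: a shared per-sample baseline correlates all features,
  and a multivariate model can estimate and subtract it using the
  unaffected segments, legitimately beating the univariate bound. The
  signal-recovery validation therefore switches the baseline off.
* **Resolution advantage needs dilution.** Fine segmentation (k = 4) beats
  coarse (k = 1) when sub-chromosomal effects are *diluted* by
  whole-chromosome averaging. If the per-event shift is large, the
  event-occurrence (Bernoulli) variance dominates the feature variance at
  both resolutions and the two perform alike; small-magnitude,
  high-contrast burden differences are the regime where resolution pays,
  and that is what the resolution check simulates.
* **Determinism.** All stochastic steps (simulation, matching order,
  splits, folds, tree learners, bootstrap, permutation shuffles) are
  seeded; xgboost and ranger run single-threaded so results are bit-stable
  across machines with the same library versions.

Validation problem sizes, chosen as the package's desk-scale study
conditions: null calibration uses a 2,000-sample cohort at 500
markers/chromosome over 5 repeated runs; signal recovery 2,500 samples;
the resolution and transfer checks use 5-seed grids at 1,100–1,500 samples.
These finish in about a minute total while leaving Monte-Carlo error well
inside the asserted bands.

## Known limitations

* Quintile odds ratios follow an explicit, documented formula; they are
  not calibrated absolute risks, and no decile/percentile calibration is
  provided beyond the `n_bins` argument.
* The greedy age matcher is not optimal matching and matches on age only.
* CNV *calling* (CBS, HMMs), BAF integration, and probe-quality weighting
  are out of scope; the feature is always a plain segment mean.
* The stacked ensemble's CV AUCs are mildly optimistic (non-nested stack),
  though its test AUCs are not.
* Real-data performance claims cannot be established with the bundled
  simulator; it exists to verify machinery, calibration, and contracts.
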