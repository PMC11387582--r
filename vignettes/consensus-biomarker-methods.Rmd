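---
title: "Methods: consensus Random-Forest biomarker discovery in paired CSF proteomics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus Random-Forest biomarker discovery in paired CSF proteomics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smaproteo)
```

## The study design this package models

`smaproteo` implements the analysis workflows for a paired-timepoint,
label-free CSF proteomics study of spinal muscular atrophy (SMA): patients
from three severity subtypes (SMA1 most severe, SMA3 mildest) sampled at
baseline (`T0`) and again after roughly ten months of treatment (`T302`),
with motor-function scores (CHOP INTEND for SMA1, HFMSE otherwise) defining
a responder label. Three questions structure the analysis, and the package
exposes one workflow per question:

1. **Baseline stratification** (`run_baseline_workflow()`): can the T0
   proteome classify severity subtype, and which proteins carry that
   signal?
2. **Treatment effect** (`run_treatment_workflow()`): which proteins change
   between T0 and T302 within each subtype, and do they split into
   coherent up- and down-regulated groups?
3. **Response** (`run_responder_workflow()`): do responders' proteome
   *changes* differ from non-responders'?

## Preprocessing and the leakage contract

Raw label-free quantification (LFQ) intensities are non-negative, with `0`
meaning "not quantified" — a missing value, not a true zero. The fixed
pipeline head is: log2 transform, per-sample median-centering over observed
values, then a completeness filter keeping proteins observed in at least
70% of samples of at least one subtype. Median-centering removes any
per-sample additive shift on the log scale *exactly*, which is why the
synthetic generator plants such shifts: a pipeline that skipped centering
would fail its tests.

Two downstream conventions differ by analysis and are deliberate:

* **Model fitting** (the classifier) needs complete data, so missing
  values are imputed with the per-protein minimum observed value — a
  conservative left-censored choice consistent with LFQ missingness being
  abundance-related in real data. Critically, imputation minima and the
  per-protein standardization (`fit_scaler()` / `apply_scaler()`) are
  estimated **on the training partition only** and then applied unchanged
  to held-out samples. `ScalerState` is a pure function of the training
  subset; tests assert that mutating test samples cannot change it.
* **Differential testing** never sees imputed values: the paired and
  responder contrasts use pairwise-complete observations, skipping a
  protein for a patient who lacks either timepoint.

Whether median-centering should be per sample or per protein is
under-determined by the phrase "median-centered intensity values" alone;
per-sample centering is the LFQ standard and is what we implement (the
per-protein location is handled later by scaling or z-scoring where
needed).

## The consensus Random-Forest selector

The core procedure is a stability selection scheme built around a
deliberately weak learner:

* a stratified 80/20 split of the T0 samples (per-subtype train counts
  `round(0.8 n)`, clipped so every subtype keeps at least one train and
  one test sample);
* a Random Forest of 1000 trees with **at most 3 terminal nodes per
  tree** — depth-limited stumps. Three leaves are exactly enough to
  separate three ordered classes on a single monotone marker, so each tree
  is forced to bet on one or two proteins rather than memorize the sample;
* per-repeat ranking of proteins by mean decrease in Gini impurity, with a
  deterministic tie-break (importance descending, then protein ID
  ascending), truncated to the top 30;
* 100 repeats with seeds 1..100, and a **strict intersection** of the 100
  top-30 lists as the consensus set. A protein in 99 of 100 lists is
  excluded; the per-protein frequency table is reported so near-misses are
  visible. A majority-vote alternative (`consensus = "majority"`) is
  provided as a configuration option, without any claim that it matches
  the original procedure.

`mtry` defaults to `floor(sqrt(p))`; the original tuning grids are not
recoverable, so the parameter is exposed but not tuned by default. Because
single-feature threshold splits are invariant to monotone per-feature
transforms, standardization does not change the trees — it is kept because
the leakage contract is about discipline, and because downstream consumers
of the scaled matrix (PCA, clustering) do depend on it.

Accuracy is the plain proportion correct on the held-out samples, with no
class balancing. On well-separated cohorts the expected behavior is
*uniform* perfect accuracy — the overfitting signature the procedure is
designed to survive — while feature selection relies on the intersection,
not on accuracy differences.

Two subtleties discovered while validating the procedure are worth
recording. First, the consensus would depend on the input row order if
ranks were broken by position, and Random Forests are themselves sensitive
to feature order at a fixed seed; `run_consensus()` therefore sorts
proteins into a canonical ID order before training, making the consensus
invariant to how the matrix was assembled. Second, strict intersection is
**not** a guarantee of emptiness under the null: the 100 training sets
share 80% of the cohort, so importance rankings are correlated across
repeats, and in roughly a quarter of pure-noise cohorts (300 proteins,
n = 60) the single most spuriously subtype-associated protein stays inside
every top-30 list. The consensus set should be read as "stable under
resampling", not "impossible under the null"; the age-correlation and
ANCOVA stages exist precisely to interrogate survivors.

## Statistical contrasts

**PERMANOVA.** Factor screening uses single-factor permutational MANOVA on
Euclidean distances: pseudo-F = (SS_between/(a−1))/(SS_within/(N−a)) from
squared distances, with p = (#{F_perm ≥ F_obs} + 1)/(n_perm + 1) under
label permutation (999 permutations by default, seeded). For n ≤ 8 an
exact mode enumerates all permutations; tests verify the sampled p
converges to the exact one and that the pseudo-F matches both an
independent Gower-trace computation and `vegan::adonis2`. Each factor is
tested marginally — one factor per test, as in the original per-factor F
list — not sequentially. Continuous age is binned into tertiles for
PERMANOVA because the test needs groups; the binning is a package choice,
exposed as a parameter, and no claim is made that it matches the original
coding.

**ANCOVA screen.** Age in this design is a confounder by construction —
more severe subtypes are younger — so the baseline differential screen
fits `abundance ~ age + subtype` per protein and tests the subtype term by
a partial F-test against the age-only model (Type-II). Significance uses
the raw p at 0.05: the screen feeds clustering and inspection, not formal
discovery claims.

**Paired treatment test.** Per subtype, a paired two-sided t-test of the
within-patient log2 change (T302 − T0), BH-adjusted within that subtype's
protein list (each subtype is analyzed individually, so the adjustment is
within-subtype). Significance at adjusted p < 0.05. Proteins with fewer
than 3 complete pairs are skipped. Zero-variance difference vectors
produce undefined t statistics; these are reported as missing p-values and
never flagged significant.

**Responder contrast.** Per subtype, the per-patient change Δ = log2
abundance(T302) − log2 abundance(T0) is compared between responders and
non-responders with an unpaired two-sided t-test — Welch by default for
robustness to unequal class variances, with a pooled-variance switch.
Significance uses the raw p, matching the exploratory character of the
small per-class sample sizes. The sign convention is global and fixed:
**positive always means higher at T302, or higher in responders**. (The
alternative subtract-T302-from-T0 orientation inverts every volcano plot;
we standardize on the orientation in which treatment-induced increases are
positive.)

**Responder labels.** SMA1: CHOP INTEND gain ≥ 4 points between T0 and
T302; SMA2/SMA3: HFMSE gain ≥ 3 points. Boundaries are inclusive; scores
are validated against the scale maxima (64 and 66).

## Clustering and PCA

Significant proteins from the paired test are z-scored per protein —
population-sd convention (divisor n), fixed so a two-value profile scales
exactly to {−1, +1} — then clustered on Euclidean distances with Ward-D2
linkage (`hclust` "ward.D2": squared distances inside the Ward criterion)
and cut at k = 2. The cluster whose members have the higher mean paired
difference is labelled "up", the other "down"; the labels are asserted,
not assumed. The merge order is tested against a brute-force
centroid-based Ward oracle, since Lance-Williams implementations are easy
to get subtly wrong. No optimal-leaf-ordering or cluster-count selection
is performed (k = 2 is part of the design).

PCA of samples is computed on centered (not scaled) protein profiles by
default, with a scaling switch; any pair of dimensions can be plotted,
because subtype structure need not lie in the first two components.

## Over-representation analysis

Gene sets come from a user-supplied GMT file. The background is **all
quantified proteins in the analyzed matrix**, not a genome-wide universe:
CSF proteomics detects a biased subset of the proteome, and enrichment
against the genome would mostly rediscover that detection bias. This
differs from typical web-service defaults and is intentional. Sets are
intersected with the background, filtered to sizes 3–500, and tested with
the upper hypergeometric tail P(X ≥ hits); fold enrichment is
(hits/|query|)/(|set|/|background|); FDR is BH across tested sets. ID
mapping to gene symbols is the user's responsibility (a two-column map
applied upstream); no web lookups are performed.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture: it is the
source of ground truth for every end-to-end test. It emulates the study's
structure — 61 patients (19/19/23 per subtype) with paired T0/T302
samples and ~1625 quantified proteins at full scale — with planted
structure in disjoint protein blocks: monotone subtype markers,
age-trending proteins with subtype-correlated ages (medians 2.1/7.7/15.3
years, making age a genuine confounder), a shared and three
subtype-specific treatment sets (half up, half down within each
subtype-specific set, so the two-cluster cut has ground truth), and a
responder-only set. Motor scores are generated so the planted responder
flags are exactly recoverable from the score-gain rules.

Intensities are simulated directly on the log2 scale as Gaussian noise
around per-protein baselines drawn from 20–35 log2 units, with per-sample
additive shifts (sd 0.3) to make median-centering non-trivial, then
exported as raw-scale values. Missingness is missing-completely-at-random
zeros (default rate 0.05). Defaults the study does not pin down — noise
sd 0.5, shift sd 0.3, the missingness rate, per-protein variance — were
chosen once as values a proteomics practitioner would call realistic for
CSF LFQ data and are not claimed to match the deposited dataset.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: intensity-dependent (left-censored) missingness
(a config extension, off by default), peptide-to-protein rollup noise,
batch structure, heavy-tailed or protein-specific variances, and
correlation between proteins beyond the per-sample shift. Recovery rates
on synthetic cohorts are upper bounds on real-data performance.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen desk scales: the
classifier harness uses 300 proteins with 20 patients per subtype (50
planted markers at 2 log2-units for the separation check; 5 markers at
2.5 for the recovery check); permutation calibration uses 200 null
datasets of 12 samples at 99 permutations; uniformity checks use 500
proteins. Exact-enumeration oracles cap at n ≤ 8 samples (PERMANOVA) and
4 proteins (Ward), where brute force is still exhaustive. Tolerances:
closed-form comparisons at 1e-12, standardization contracts at 1e-9,
stochastic checks at 3–5 standard errors of the quantity under test.
Degenerate inputs (constant proteins, single-class partitions, empty
queries, all-identical profiles) error or drop with warnings rather than
propagating NaN.

## Known limitations

* The strict-intersection consensus inherits the null behavior described
  above; its size is also non-increasing in the number of repeats, so
  comparisons across configurations with different repeat counts are not
  meaningful.
* PERMANOVA on tertile-binned age loses information relative to a
  distance-based covariate test; the binning is a screening convenience.
* Welch degrees of freedom with per-class n around 5–10 make the
  responder contrast exploratory; the raw-p threshold is a screen, not an
  error-rate guarantee.
* The generator's MCAR missingness makes minimum-imputation benign; under
  real left-censored missingness the classifier's imputation choice would
  deserve a sensitivity analysis.
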