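---
title: "Resting-state EEG microstate analysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Spontaneous EEG does not wander continuously through topography space:
for periods of roughly 60–120 ms the spatial configuration of the scalp
potential stays quasi-stable, then switches abruptly to another
configuration.  These quasi-stable periods — *microstates* — are
conventionally reduced to four canonical classes, labelled A (right-frontal
to left-posterior gradient), B (the mirrored diagonal), C
(anterior–posterior) and D (fronto-central extreme).  Because spontaneous
activity is not phase-locked to any event, a topography and its
sign-flipped copy count as the same state; every similarity computation in
this package is therefore polarity-invariant (the absolute spatial
correlation, or its square).

The analysis chain implemented here is the standard one for clinical
resting-state recordings:

1. average re-reference;
2. zero-phase 2–20 Hz band-pass (order-4 Butterworth, forward–backward),
   applied per epoch because epochs are excised from a longer recording
   and are not continuous across their boundaries;
3. trimming every subject to the same analyzed length, so that occurrence
   and coverage are comparable;
4. global field power (GFP) — the instantaneous population standard
   deviation across electrodes — and its local maxima, the time points of
   highest topographic signal-to-noise ratio;
5. polarity-invariant AAHC clustering of the GFP-peak maps into K = 4
   classes per subject;
6. group grand means, the grand grand mean across groups, sorting of the
   grand grand mean against canonical norm maps and of every lower level
   against the level above (exhaustive search over the K! class
   permutations, sign-aligned);
7. backfitting of each subject's sorted templates: class membership is
   decided at GFP peaks by best absolute correlation and interpolated to
   intermediate samples by nearest peak (midpoint split; an equidistant
   sample goes to the later peak);
8. parameter quantification with truncated microstates — segments cut by
   an epoch boundary, whose true life span is unknown — refused for the
   duration statistic;
9. group statistics: mixed ANOVAs, Welch t tests, Bonferroni-corrected
   transition comparisons and a randomization TANOVA.

## AAHC and global explained variance

Global explained variance (GEV) weighs each map's squared correlation
with its class template by its squared GFP:

$$\mathrm{GEV}_k=\frac{\sum_{t:\,a(t)=k}\big(\mathrm{GFP}_t\cdot
\mathrm{corr}(v_t,u_k)\big)^2}{\sum_t \mathrm{GFP}_t^2}.$$

Atomize-and-agglomerate hierarchical clustering starts from every map as
its own cluster and repeatedly dissolves the *worst* cluster, reassigning
each orphaned map to the cluster whose template it matches best; affected
templates are recomputed as the dominant spatial component of their
members (the first principal direction of the GFP²-weighted scatter,
which is exactly the template maximizing the cluster's GEV contribution),
sign-aligned to the weighted majority of members.

Two design choices here were genuinely open:

* **Template update.**  The dominant spatial component rather than a
  plain average: averaging polarity-mixed members can cancel; the
  principal direction is polarity-proof and GEV-optimal for the fixed
  membership.
* **Which cluster to dissolve.**  Ranking clusters by raw GEV
  contribution has a failure mode near the end of the agglomeration: when
  one genuine class happens to carry systematically lower GFP weight than
  the fragments of another class, the greedy dissolves the genuine class
  and its scattered members can never re-merge, costing 10–20% of the
  attainable GEV.  The dissolution criterion used here is therefore the
  *net* cost — the cluster's contribution minus the GEV its members
  recover in the clusters that absorb them.  The net term is evaluated
  exactly once at most 50 clusters remain (the regime where the failure
  mode lives); with more clusters the dissolved cluster is always a
  near-duplicate of some survivor, the regain almost cancels the loss,
  and the raw contribution is an accurate, much cheaper surrogate.  On
  small instances where the optimum is computable by exhaustive
  enumeration over all partitions (see
  `exhaustive_partition_gev()`), this rule attains the optimum on all
  tested instances, while the raw-contribution rule fell below 95% of it
  on roughly one instance in ten.  A *known limitation* remains: under
  artificially extreme weight spreads (squared-weight ratios of an order
  of magnitude and more, far outside what GFP peaks of real or simulated
  EEG produce) the greedy can still be led astray.
* **Final assignment.**  After the loop, maps are assigned once more to
  their best-matching final template, so the reported GEV is exactly the
  GEV that backfitting those templates achieves — the two quantities are
  interchangeable in reports.

Ties throughout (equal dissolution cost, equal correlation, equal
sorting objective) resolve deterministically: fewer members first, then
lower index, first maximum, lexicographically smallest permutation.

## The synthetic cohort

The clinical recordings behind the motivating analysis are not publicly
deposited, so the package ships a generator whose defaults *are* the
study conditions: a 25-electrode clinical (IFCN) montage at 250 Hz, eight
artifact-free 20 s eyes-closed epochs per subject, four canonical
classes, and quasi-stable dynamics in the reported 60–120 ms range.

* **State dynamics** are semi-Markov: classes follow a row-stochastic
  transition matrix with zero diagonal (uniform off-diagonal by default),
  and dwell times are gamma-distributed with configurable per-class mean
  (default 80 ms) and shape (default 4, giving a realistic 60–120 ms
  spread; `Inf` degenerates to fixed dwells for exact tests).  The gamma
  choice is the package's own: strictly positive, unimodal, two
  interpretable parameters; no generative model is prescribed by the
  literature.
* **Signal**: each sample is `amplitude[class] · sin(2π·10 Hz·t + φ) ·
  template[class]`; the phase φ is re-drawn uniformly at each segment
  onset so that state changes are marked by topography change, not phase
  continuity.  The default amplitude of 25 µV yields mean GFP values of
  a few microvolts, as in clinical recordings.
* **Noise** is spatially and temporally white Gaussian, scaled so that
  the state-signal RMS over noise RMS equals the configured `snr`
  (default 2).  Real EEG noise is spatially correlated and
  non-stationary; this generator makes no attempt to model blinks,
  muscle, or electrode drift, because the emulated recordings had been
  manually cleaned.  Passing tests therefore demonstrate correctness of
  the *analysis machinery* under controlled conditions, not robustness
  to real-world artifacts.
* **Between-subject variance**: lognormal multipliers (σ = 0.1) jitter
  each subject's dwell and amplitude, giving the ANOVA layer realistic
  heterogeneity.  Group effects are multiplicative deltas on dwell and
  amplitude and additive (re-normalized) deltas on transition rows.

One property of the generator matters for interpreting recovery numbers:
with a 10 Hz carrier, GFP peaks arrive every ~50 ms, so segments shorter
than the inter-peak spacing may contain no peak at all and are absorbed
by their neighbours during backfitting.  Recovered durations are
therefore biased a few milliseconds upward of the configured dwell
(≈86 ms recovered at 80 ms configured under the default conditions); the
recovery tests use the ±10 ms band that this resolution limit implies.

## Statistics

* **Mixed ANOVA** (between: group; within: class) uses the classical
  split-plot decomposition.  Mauchly's test runs on the pooled
  within-group covariance of the class values; when sphericity is
  rejected at α = 0.05, the Greenhouse–Geisser ε (bounded to
  [1/(K−1), 1]) rescales the within-effect degrees of freedom.
  Huynh–Feldt is deliberately not offered.  Effect sizes are partial η²
  against each effect's own error stratum.
* **Welch t tests** (two-tailed, unequal variances,
  Welch–Satterthwaite df) compare "overall" parameter levels pooled over
  subject × class observations — the pooling that reproduces the
  fractional dfs near 160 seen in two-group comparisons of 2 × 21 × 4
  observations — with Cohen's d pooled by n−1 weighting.
* **Transition syntax**: per-subject relative transition percentages
  (12 ordered pairs for K = 4), compared by Welch tests with Bonferroni
  m = 12.  Subjects with no transitions out of a class are dropped from
  that pair only.  Truncated segments count towards transitions and
  occurrence under the default `"duration-only"` policy (the denser
  convention; `"strict"` excludes them everywhere).
* **TANOVA**: subject maps are normalized to unit GFP, the observed
  effect is the GFP of the group-mean difference map, and the null
  distribution comes from reshuffling subjects between groups with group
  sizes preserved.  The default is 5000 permutations and the add-one
  estimator `p = (1 + #{perm ≥ obs}) / (1 + n)`, which cannot return 0.
  Because which maps enter such a test is ambiguous in practice, both
  entry points are computed: per-subject mean maps and the per-class
  variant on sorted individual templates.
* **Outlier screen**: per parameter, per class, a subject whose value
  leaves its group's mean ± 3 SD band is excluded from that parameter's
  analyses — a single pass, never iterated, and never propagated to
  other parameters.

## Numerical conventions and degenerate inputs

* GFP and TANOVA use the population (1/E) standard deviation, the
  convention of the microstate literature; the divisor is stated because
  it is not universal.
* GFP peak detection requires a strict rise and a strictly lower next
  *distinct* value; a plateau yields its first sample; runs touching an
  epoch edge yield no peak.
* Zero-variance peak maps are skipped with a warning during clustering
  and backfitting; an epoch without peaks stays unassigned; a class with
  no qualifying segment records a missing (not zero) duration.
* Constant data in the ANOVA produce F = 0, p = 1 (sums of squares below
  numerical noise are treated as zero); zero variance in both Welch
  samples with equal means gives t = 0, p = 1, and is an error when the
  means differ (within `compare_transitions` such a pair reports NA
  rather than aborting the battery).
* All stochastic components (cohort generation, permutation tests) take
  explicit seeds; pipelines are bit-reproducible from config plus seeds.

## Problem sizes

The package's own verification runs use: recovery cohorts of 10
subjects/group at the full 8 × 20 s per subject; effect-detection
cohorts of 20 subjects/group; 500 null simulations for type-I-error
calibration of the TANOVA (1000 permutations each) and the mixed ANOVA;
100 random instances for the GEV oracle comparison; and 20 twelve-map
instances for the exhaustive-partition optimality check.  The
`analysis/` scripts run the full study-scale cohort (21 subjects per
group).

## What the package does not do

No artifact detection or ICA; no resampling; no modified k-means or
other clustering back-ends (AAHC only); no cross-validation choice of K
(K = 4 fixed); no Bayesian or equivalence re-analyses; no GUI.  The
canonical "norm" maps used for sorting are analytic stand-ins
constructed from electrode geometry — adequate for orienting synthetic
cohorts whose ground truth is built from the same family, and
replaceable by a user-supplied measured norm set via
`pipeline_config(norms = read_template_set(...))` for work with real
recordings.
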