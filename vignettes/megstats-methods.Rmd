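---
title: "Spatiotemporal inference on MEG source estimates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal inference on MEG source estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`megstats` analyses trial-level MEG source estimates — dense
`trials x sources x time` tensors in arbitrary dSPM-like units — from a
two-word reading paradigm with a 2 x 2 design (associative strength low/high
x compositionality phrase/list) plus a single-word visual baseline.  Four
statistical procedures are provided, each exercisable end to end on synthetic
data:

1. **Mass-univariate two-stage regression.**  Per subject, an ordinary
   least-squares regression of every (source, time) point on condition
   predictors and word-frequency covariates; across subjects, a one-sample t
   test of each coefficient against zero, corrected by threshold-free cluster
   enhancement (TFCE) with sign-flip max-statistic permutations.
2. **Searchlight pairwise decoding.**  Linear SVM classification of condition
   pairs from pseudo-trial patterns in sliding neighborhoods (k
   graph-nearest sources x consecutive decimated samples), tested against the
   50% chance level with a one-tailed TFCE permutation test.
3. **RDM-based directed connectivity.**  Time-resolved representational
   dissimilarity matrices (1 minus Pearson correlation between
   condition-mean patterns) per functional ROI; directed flow from region A
   to B quantified as the partial correlation between A's past RDM and B's
   current RDM, partialling out B's own past, over a lag x time grid; the
   A→B − B→A contrast tested by sign-flip permutation.
4. **Embedding-based association scoring.**  Cosine similarity between
   GloVe-style word vectors (with a PCA-reduced variant) and the
   high (> 0.3) / low (< 0.15) / excluded labeling of word pairs.

# The model and its assumptions

## Two-stage regression

The first stage treats every grid point independently:
\(y_{i} = X \beta + \varepsilon_i\) per subject, with predictors
`intercept, association, composition, interaction, n_words` and centered
`word1_logfreq, word2_logfreq` covariates.  Factors are dummy coded (0/1)
with the single-word condition at the origin; an effect-coded (±0.5) variant
is available and the planted-contrast estimate is invariant to the choice.
Word-frequency columns are centered within subject so condition coefficients
are evaluated at mean frequency.  A mixed-effects model per point would be
statistically richer but is impractical at the grid sizes involved; the
two-stage scheme treats the subject as the unit of inference, which is what
the second-stage sign-flip test assumes (symmetric subject effects under the
null).

## TFCE and permutation inference

For a statistic map \(h(p)\) on a graph x time grid, the enhancement is
\(\mathrm{TFCE}(p) = \int_{h_0}^{h(p)} e(h)^E\, h^H \, dh\), where \(e(h)\)
is the extent of the connected component containing \(p\) after thresholding
at \(h\).  Connectivity is the spatial adjacency graph within a time sample
plus the same source at adjacent samples (no diagonal space-time edges).
Exponents default to the literature-standard \(E = 0.5\), \(H = 2\); the
threshold origin is \(h_0 = 0\).  The negative tail is enhanced on the
negated map and subtracted, so two-sided maps are signed.

**Numerical choices.**  The integral is evaluated by a midpoint rule with
step `dh` (default: the map's tail maximum divided by 100), plus an exact
correction for the partial interval between the last midpoint and each
point's own statistic value.  The test suite checks the implementation
against an independent brute-force threshold sweep at one tenth of the step,
with per-threshold component labeling in igraph; agreement is required to 1%
of the map's TFCE scale.  (Strict per-point relative error is not a
meaningful yardstick for quadratures at different steps: a point whose
statistic lies below the first coarse threshold receives zero from the
coarse sum and a positive value from the fine one.)  The enhancement sweep is
implemented in C++ with an incremental union-find over descending
thresholds; inside the permutation loop the t statistic is clamped to 1e6 so
degenerate zero-variance points cannot produce non-finite maps.

The null is generated by independently flipping each subject's deviation
from the null mean — the conventional one-sample sign-flip scheme.  A
literal "zero-exchange" variant (replacing a subject's value by the null
mean) is available behind `nullMethod = "zero"` for sensitivity analysis.
Family-wise control uses the permutation distribution of the maximum
(absolute) TFCE score over the grid, the standard pairing with TFCE; an
uncorrected per-point option exists.  P-values use the add-one estimator
\((1 + \#\{\text{exceedances}\})/(1 + n_{\mathrm{perm}})\), which never
returns 0 and keeps the test valid at any permutation count.  Regression
tests default to two-sided (the tail convention for coefficients is not
dictated by the decoding analysis, which is explicitly one-tailed); the
choice is recorded in each result's metadata.

## Searchlight decoding

Preprocessing happens once and is shared with connectivity: the fitted
contribution of the two frequency covariates is subtracted at every grid
point, then the time axis is decimated by taking every k-th sample (factor 5
in the reference pipeline; the data are assumed low-passed upstream — a
block-mean variant is available).  Each condition's trials are averaged into
`nPseudo` pseudo-trials (random disjoint partition; remainder trials are
assigned round-robin so block sizes differ by at most one; 60 trials → 15
blocks of 4, 45 → 15 blocks of 3).

"Radius of 100 sources" is read as a count: the 100 graph-nearest sources by
breadth-first hop distance within the analysis mask, ties broken by source
index, crossed with 5 consecutive decimated samples centered on the center
(truncated at window edges).  Per cross-validation repetition the partition
is redrawn, one pseudo-trial per condition is held out, and a linear SVM
(unit cost — the conventional default; regularization is not a tuned
quantity here) is trained on the remainder; features are standardized by
training-fold statistics only, which both prevents leakage and makes
accuracies invariant to global rescaling of the data.  Within a repetition
the partition and held-out indices are shared across centers and pairs
(repartition-then-scan), matching how a per-permutation repartition is used
in practice.  The four pairings compare composition within each association
level and association within each composition level.  Group inference is a
one-tailed test against 0.5 via the same TFCE permutation machinery.

## Directed connectivity

At each decimated time point the item patterns of a region are the
condition-mean source patterns over pseudo-trials (4 items, 6 RDM entries;
a pseudo-trial-level granularity — 60 items — is exposed as an option, and
both are exercised by the tests).  Dissimilarity is 1 − Pearson r across
the region's sources, so entries live in [0, 2] and are invariant to
positive rescaling of the data.  Undefined correlations (constant patterns)
are imputed as dissimilarity 1 — and partial-correlation cells with a
constant input as 0 — with warnings, rather than propagating missingness
into the group test.  The flow statistic
\(pc[t, dt] = \mathrm{pcor}(D_A(t-dt),\, D_B(t) \mid D_B(t-dt))\) is
computed per subject over a lag grid (5…600 ms in 5 ms steps in the
reference configuration, snapped to the decimated sample step) and the
direction contrast A→B − B→A is tested two-sided on the lag x time grid
with 4-neighborhood connectivity.  With only 6 RDM entries a single partial
correlation is noisy; the procedure relies on subject-level averaging, which
is why the contrast is computed per subject and tested across subjects.

## Association scoring

PCA for the reduced-dimension cosine variant is fitted on the stimulus
vocabulary (the distinct tokens of the scored pairs) rather than a full
corpus vocabulary — the fitting population is recorded in the output, and a
different population can be supplied.  Embedding files are external inputs
in GloVe whitespace-text format; the package ships a small deterministic
synthetic embedding fixture (`inst/extdata/glove_toy_synthetic.txt`) so all
tests run offline.  Scores on real embedding releases are version-dependent.

# The synthetic-data generator

The generator emulates the study conditions: five conditions (2 x 2 plus
single-word), epochs [−100, 1200) ms at 1000 Hz relative to first-word
onset, second word at 600 ms, 60 trials per condition (experiment 1) or 45
(experiment 2), and cohorts of 21 subjects.  Its components:

- **Planted univariate effects**: an amplitude tied to a design predictor,
  added inside a region x window, so condition-mean contrasts of noiseless
  data reproduce planted amplitudes to machine precision.
  `amplitudeForT()` converts a target single-subject t (e.g. 5) into an
  amplitude given the design and noise SD.
- **Planted multivariate patterns**: a temporally smoothed random field added
  with opposite signs to the two conditions of a pair contrast, or (for
  connectivity simulations) one field per condition
  (`"condition-patterns"`), giving the RDMs time-varying structure that a
  purely univariate plant cannot provide.
- **Couplings**: the target region receives a gain-scaled, lag-shifted copy
  of the source region's noise-free signal (index-matched when the regions
  have equal sizes, otherwise through a fixed seeded random projection), so
  lagged correlations peak exactly at the planted lag in noiseless data.
- **Frequency covariates**: log10 frequencies are drawn per two-word trial
  from Normal(2, 0.8) (a realistic per-million log-frequency scale; the
  single-word trials carry no first word and get 0).  They are always
  recorded; mixing them into the signal is an explicit `freqEffect`
  specification — a scalar gain on a fixed spatial pattern with negative
  default slopes (−0.5 per log10 unit), so more frequent words evoke less
  activation.  With no planted effects and zero noise the generator returns
  exactly zero tensors.
- **Noise**: white noise smoothed by graph diffusion
  (`spatialCorrLength` steps of averaging with neighbor means) and a
  temporal moving average (`temporalSmoothingMs`), then rescaled so the
  empirical SD equals `sensorSd`.  Subject heterogeneity is an additive
  per-subject offset on planted amplitudes (SD `subjectSd`); no per-subject
  spatial deformation, which keeps recovery tests interpretable.
- **Dropout**: an optional per-trial rejection rate (the reference pipeline
  rejects ≈9% of epochs); at least two trials per condition are kept.

What the generator does **not** emulate: realistic cortical geometry and
source leakage from an inverse solution, 1/f spectra and oscillatory
structure, eye/muscle artifacts, or subject-specific functional topography.
Passing recovery tests therefore demonstrate that the statistics detect what
they claim to detect under controlled conditions — not that any particular
real dataset will show those effects.

# Test and acceptance problem sizes

Simulation-based checks run at reduced sizes chosen to keep the full suite
within a desktop budget while leaving the statistical claims meaningful;
they are the package's own choices:

- **Error calibration (regression)**: 200 null datasets, 12 subjects,
  80 sources x 120 samples, 200 permutations; the family-wise positive rate
  must fall in the 95% binomial interval around 0.05.
- **Effect recovery (regression)**: 20 seeds, 12 subjects, 60 sources,
  amplitude set for a first-stage t ≈ 5, 500 permutations; Dice ≥ 0.5
  against the planted set, correct sign, and no detections at sources more
  than one hop from the planted region, in at least 18 of 20 seeds.
- **Decoding**: 12 subjects, 64 sources, reduced searchlight density
  (stride-thinned centers, 12-source neighborhoods), 8 repartitions.  The
  planted HA-comp/LA-comp pattern (±pattern on those two conditions) must be
  significant at centers inside its region; the untouched HA-list/LA-list
  pair and all centers whose neighborhoods avoid the region must stay null.
  Note a geometric fact: the four tested pairings form a cycle over the
  conditions, so no additive condition-pattern assignment can make exactly
  one pairing decodable — the two pairings sharing one planted condition
  carry half the separation by construction and are therefore not part of
  the exclusivity check.
- **Connectivity**: planted A→B coupling at 100 ms recovered with positive
  sign and median significant lag within ±50 ms; reversing the plant flips
  the sign; 100 independent-noise control runs (the adjacent-region null
  analogue) must be free of significant cells in at least 95 runs at
  α = 0.05 — a deliberately tight check, since an exactly calibrated test
  passes it with modest probability.
- **Demo**: the shipped `demo_config.yaml` (8 subjects, 64 sources, 250 Hz,
  reduced permutation counts) runs the full pipeline twice and must produce
  bit-identical outputs well inside 15 minutes on one CPU.  Its planted
  amplitudes are set high enough that each stage shows its intended positive
  finding at this reduced size.

# Determinism and provenance

Every stochastic stage takes an explicit seed; run configurations without a
seed per stage are refused at validation.  Seeds for subjects, repetitions
and permutations are derived deterministically from the stage seed.  All
containers (binary doubles plus a JSON sidecar) embed the MD5 hash of the
producing configuration; the provenance log records seeds, package version,
and, for every inference, the test, tail, permutation count and correction
used.  Numeric payloads (including covariates and time axes) live in the
binary file so round-trips are bit-exact.

# Known limitations

- TFCE `dh` defaults to max(stat)/100 per map; maps whose interesting
  structure sits far below the maximum receive a coarser effective
  integration there.  Fix `dh` explicitly when comparing maps across
  datasets, and note that the monotonicity property of TFCE holds for a
  fixed `dh`, not under the per-map automatic step.
- The searchlight recomputes pseudo-trials per repetition at the subject
  level; with very few trials per condition the partitions overlap heavily
  and repetitions are correlated — accuracies remain valid but their
  variance is underestimated by the repetition count.
- Flow grids mark lag cells that precede the epoch as missing and exclude
  them from sign-flip inference by zero-filling (with a warning); under the
  default epoch/window geometry no such cells occur.
- The RDM condition granularity uses 6 dissimilarity entries; partial
  correlations over 6 values are individually noisy and only the
  subject-averaged contrast is interpretable.
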