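---
title: "Multi-scale lagged co-activation features: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale lagged co-activation features: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscalefc)
```

## The model

`mscalefc` turns one subject's region-averaged BOLD matrix (M time
points × N regions) into a discrete probability distribution over
*lagged co-activations*. The pipeline rests on three assumptions:

* **High BOLD values mark neural activity.** Because of the BOLD imaging
  principle, supra-threshold time points are the informative ones, so
  each region's series is reduced to a 0/1 activity sequence. The cutoff
  is per-region and data-driven — th(T_i) = μ(T_i) + η·σ(T_i), the
  three-sigma rule — which makes binarization exactly invariant under
  any positive affine rescaling of the raw signal (units, scanner gain
  and baseline shifts drop out). σ uses the sample divisor M − 1, and a
  value *equal* to the threshold counts as active.
* **Disease-relevant coupling need not be synchronous.** Co-activations
  are counted for every *ordered* pair (i, j) at every lag l inside a
  set of closed intervals, default {[0,0], [1,1], [2,2], [3,12]}:
  synchrony, two sharp short lags, and one loose long-range window.
  Near-zero lags deserve their own intervals because co-activation
  statistics change quickly there; distant lags are pooled because
  individual long lags are noisy and pooling trades resolution for
  stability. A positive lag means the *second* region follows the first,
  so the count tensor is directional; the lag-0 slice is exactly
  symmetric by construction.
* **Proportions, not raw counts, are comparable across subjects.**
  Dividing the N × N × T tensor by its grand total yields the fraction
  of a subject's co-activations on each (pair, interval) cell,
  normalizing away differences in overall activity level and (partly)
  scan length.

The flattened distribution is the feature vector (N²·T entries; feature
names encode `src|dst|lo-hi`). The synchronous Pearson-correlation
baseline (N(N−1)/2 upper-triangle entries) and the concatenation of the
two are the other feature kinds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eta` | 1 | threshold multiplier, in per-region SD units. Larger values mark fewer, more extreme time points as active; 1 keeps roughly the top sixth of a Gaussian-like series. |
| `intervals` | `[0,0],[1,1],[2,2],[3,12]` | lag intervals in volumes (TR units). More/narrower intervals give finer temporal detail but sparser counts and a larger feature space. |
| `excludeDiagonal` | `FALSE` | whether to drop i = j cells. The diagonal measures each region's own activity persistence; it is kept by default because the distribution is defined over all ordered pairs, and a switch exists for ablation. |
| `selection.alpha` | 0.05 | per-feature two-sample t-test threshold, no multiple-testing correction (plain p < 0.05 rule; a Benjamini–Hochberg switch exists). |
| `classifier` | linear SVM, C = 1 | no tuning grid is applied anywhere; logistic regression and random forest (500 trees) are drop-in comparators. |

## Selection placement

Feature selection runs *inside* each leave-one-out training fold by
default: the held-out subject never touches the p-values that choose its
fold's features (the test suite asserts this by corrupting a held-out
row and checking the fold's selection is unchanged). Selection once on
the full cohort (`selectWithinFold = FALSE`) is also available because
it is common in the literature; it leaks the test subject into
selection and typically inflates accuracy, which is why it is not the
default. A fold in which no feature clears `alpha` falls back to the
single smallest-p feature, since a classifier cannot train on zero
columns.

## Numerical choices and degenerate inputs

* **Boundary truncation.** Lagged terms that would read past the end of
  the series (m + l > M) are skipped. No padding scheme is imposed; skip
  adds no fabricated co-activations and keeps every count an honest
  event tally.
* **Zero-variance features.** A feature with zero variance in both
  groups has an undefined t statistic; it receives p = 1 and is never
  selected.
* **Degenerate subjects.** A subject with no co-activations at all
  yields an all-zero feature vector and a warning rather than aborting a
  cohort run.
* **AUC.** Computed as the rank statistic — the probability a random
  patient's decision score exceeds a random control's, ties counted one
  half — so it is invariant to monotone transforms of the scores and
  identical for decision values and calibrated probabilities.
* **SVM decision kernel.** The classifier contract is the standard
  soft-margin decision function; the kernel applied to the feature
  vectors is linear by default (RBF optional). Features are standardized
  inside the SVM fit, as is conventional.
* **Patient is the positive class** throughout, which fixes the meaning
  of sensitivity and specificity.

## What the synthetic generator emulates

`generateCohort()` draws, per region: AR(1) Gaussian baseline noise
(unit innovation SD, coefficient `noiseAR`), spontaneous activation
events (probability `eventRate` per time point, each adding
`amplitude`, in noise-SD units), and — for each coupling whose group
matches the subject's label — an induced activation of the target
region `lag` volumes after each source event with probability
`strength`. Every subject uses a child seed drawn from the master seed,
so cohorts are byte-reproducible while subjects stay independent.

Activation is an additive bump rather than a hemodynamic-response
convolution: the feature pipeline only consumes supra-threshold states,
so bumps are the minimal structure that exercises thresholding,
co-activation counting and normalization; an HRF-convolution layer is a
documented extension point, not a default. The generator therefore does
*not* emulate slow hemodynamic smearing, head motion, physiological
noise spectra, or spatial correlation between neighboring regions —
passing tests show the pipeline recovers planted lag structure under
realistic noise, not that it will reach any particular accuracy on
clinical data.

The defaults define the package's reference simulation: 31 patients +
29 controls (a 60-subject, single-site clinical scale), 20 regions ×
150 volumes, `eventRate` 0.08 (a region is "on" a few times per
100 volumes, sparse as expected for discrete supra-threshold events),
`amplitude` 5 (events clear the threshold decisively but do not dwarf
the noise), `noiseAR` 0.3 (moderate temporal smoothness typical of
band-passed BOLD), and five patient-only couplings at lags 1–3 with
strength 0.8. Because the two groups differ *only* in lagged couplings,
this design isolates the package's central claim: lag-aware features
separate the groups while synchronous correlation cannot.

## Problem sizes used by the test suite

The suite favors many small cohorts over one large one: oracle
equivalence is checked against an exhaustive triple-loop on 100 random
instances (N ≤ 5, M ≤ 20); null calibration uses fifty 60-subject
cohorts of 10 regions × 60 volumes with identical generative parameters
in both groups; the discrimination comparison uses ten seeds of the
reference simulation above. These sizes give stable Monte-Carlo
estimates while keeping a full run in well under a minute per property.

## Known limitations

* Counts at long lags pool many offsets; the [3,12] interval cannot
  localize *which* lag carries signal.
* Normalization couples cells: increasing mass on one pair necessarily
  decreases the proportion elsewhere, so single-cell group contrasts
  should be read as relative, not absolute, effects.
* Logistic regression is fit unpenalized; with more selected features
  than subjects it relies on the fitter's aliasing of redundant columns
  and is included as a comparator, not a recommendation.
* LOOCV on small cohorts has high variance; the chance band used for
  null calibration (mean accuracy 0.4–0.6 across seeds) reflects that.
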