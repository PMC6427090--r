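# mscalefc

Multi-scale functional connectivity features for brain-disease
classification from region-averaged fMRI time series.

## The problem

Resting-state fMRI studies summarize each subject as an M × N matrix: M
time points of the BOLD signal averaged over each of N atlas regions
(116 for the AAL atlas). The standard functional-connectivity feature is
the Pearson correlation of every region pair — but correlation is
synchronous by construction, so any *lagged* dependence between regions
(region j tending to activate a few volumes after region i) is invisible
to it. `mscalefc` implements a feature set that captures exactly that
lagged structure, for researchers building classifiers that separate
patients from controls.

## The method

For one subject with region series T_1 … T_N:

1. **Dynamic-threshold binarization.** Each region gets its own
   activation cutoff th(T_i) = μ(T_i) + η·σ(T_i) (three-sigma rule; σ is
   the sample SD with divisor M − 1, η = 1 by default). Time points at or
   above the cutoff are "active" (state 1).
2. **Lag-interval co-activation counts.** For every ordered region pair
   (i, j) and every closed lag interval I_t = [r_t, s_t] in the set
   I = {[0,0], [1,1], [2,2], [3,12]},

       C(i, j, I_t) = Σ_m Σ_{l = r_t..s_t} 1[ i active at m AND j active at m + l ],

   with out-of-range terms (m + l > M) skipped. C is a 3-order N × N × T
   tensor and is directional: C(i, j, I_t) ≠ C(j, i, I_t) in general.
3. **Probability normalization.** P(i, j, I_t) = C(i, j, I_t) / ΣC, the
   proportion of all observed co-activations falling on each (pair, lag)
   cell. Flattened, this gives N²·T features per subject (53,824 for
   AAL-116 with the default four intervals), alongside the N(N−1)/2
   synchronous PCC baseline features (6,670 for AAL-116) and their
   concatenation.
4. **Selection and classification.** Per-feature two-sample t tests
   (p < 0.05) select features inside each training fold; an SVM (linear
   kernel, C = 1; logistic regression and random forest as alternatives)
   is evaluated by leave-one-out cross-validation with accuracy,
   sensitivity, specificity and rank-based AUC (patient = positive
   class).

A synthetic cohort generator (AR(1) BOLD-like noise + spontaneous
activation events + directed, lag-specific, group-dependent couplings)
makes the whole pipeline testable without clinical data.

## Worked example

A 60-subject cohort whose groups differ *only* in five patient-only
lagged couplings (lags 1–3), so synchronous correlation carries no group
signal:

```r
library(mscalefc)

co <- generateCohort(SyntheticSpec(seed = 1))
co
#> SyntheticCohort: 60 subjects, 20 regions x 150 time points

fm <- extractFeatures(co, "multiscale_fc")
fm
#> FeatureMatrix [multiscale_fc]: 60 subjects x 1600 features

loocvEvaluate(fm, cohortManifest(co))
#> EvalResult (60 subjects, LOOCV)
#>   accuracy 0.9333  sensitivity 0.9355  specificity 0.9310  auc 0.9900

fp <- extractFeatures(co, "pcc")
loocvEvaluate(fp, cohortManifest(co))
#> EvalResult (60 subjects, LOOCV)
#>   accuracy 0.4500  sensitivity 0.4839  specificity 0.4138  auc 0.4416
```

The lagged features recover the group difference almost perfectly
(93% LOOCV accuracy) while the synchronous PCC baseline stays at chance —
the construction guarantees there is nothing synchronous to find.

A command-line front end is installed with the package
(`system.file("cli", "mscale-fc", package = "mscalefc")`) with
subcommands `simulate`, `extract`, `evaluate` and `run-all` driven by a
YAML config; see `?readPipelineConfig`.

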