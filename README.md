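# sleepwave

Automated six-class sleep-stage scoring (W, S1, S2, S3, S4, REM) from
30-second EEG epochs, built around a purpose-designed **linear-phase optimal
biorthogonal wavelet filter bank whose analysis lowpass is a halfband
filter**.

Clinicians score overnight polysomnography by hand, epoch by epoch — slow,
expensive, and error-prone. `sleepwave` implements an automated alternative
for single- or dual-channel EEG (F4-C4, C4-A1 at 512 Hz): each epoch is
decomposed into six frequency sub-bands by a five-level wavelet transform,
the l1/l2/l∞ norms of the sub-band coefficients form the feature vector
(18 per channel, 36 combined), and an ensemble of bagged CART trees
classifies the stages under repeated stratified 10-fold cross-validation
with confusion matrices, Cohen's κ, per-class one-vs-rest accuracy, F1 and
ROC/AUC. A stage-conditioned synthetic EEG generator makes the whole
pipeline testable without access to a sleep database.

## The core method

The analysis lowpass `h0` (odd length L) is halfband — center tap 1/2,
even-offset taps exactly zero — with zero-phase amplitude
A(ω) = 1/2 + 2 Σₖ aₖ cos((2k−1)ω), so A(ω) + A(π−ω) = 1. The free taps
minimize a convex combination of stopband energy and time–frequency
concentration,

    J(a) = α ∫_{π−ωp}^{π} A(ω)² dω + γ (D_t(a) + D_ω(a)),

subject to R regularity constraints (zeros of A at π), solved exactly as an
equality-constrained quadratic program (eigenfilter style). The synthesis
lowpass `f0` minimizes the same objective subject to perfect reconstruction
— the product filter h0∗f0 must be halfband — plus V vanishing moments.
Highpass filters follow by modulation, and a one-level reconstruction
self-test is part of the constructor. With all freedom spent on regularity
the designs collapse to the classical maxflat halfband filters
(length 7: [−1, 0, 9, 16, 9, 0, −1]/32).

## Worked example

```r
library(sleepwave)

# design the default bank: halfband analysis L = 11, synthesis M = 17
bank <- default_filter_bank()
verify_halfband(bank$h0$taps)        # 0 — structural zeros are exact

# synthetic cohort: 20 epochs per stage, two channels at 512 Hz
spec <- cohort_spec(list(healthy = setNames(rep(20, 6), stage_levels())),
                    fs = 512, epoch_s = 30, seed = 7)
cohort <- generate_cohort(spec)
fm <- build_feature_matrix(cohort, bank)        # 120 x 36 features

cv <- repeated_cv(fm, fm$label, n_learners = 30, k = 10, trials = 2, seed = 7)
cv
#> Repeated 10-fold CV, 2 trial(s):
#>   accuracy = 100.0 +/- 0.00 %
#>   kappa    = 1.0000 +/- 0.0000
#>   per-class (one-vs-rest):
#>   class ovr_accuracy f1 auc
#> 1     W          100  1   1
#> 2    S1          100  1   1
#> 3    S2          100  1   1
#> 4    S3          100  1   1
#> 5    S4          100  1   1
#> 6   REM          100  1   1
```

Synthetic stages have stationary, well-separated spectra, so the ensemble
sits at ceiling here; the numbers demonstrate the pipeline's wiring, not
clinical performance (see the methods vignette,
`vignettes/sleep-scoring-methods.Rmd`). On the published reference tables
the same metric code reproduces the printed arithmetic, e.g.:

```r
tab <- cap_confusion_table("insomnia_balanced")
cm <- cm_from_row_percent(tab$pct, tab$row_totals)
overall_accuracy(cm)   # 92.897  (printed: 92.8%)
cohens_kappa(cm)       # 0.9148  (printed: 0.9145)
```

Real recordings enter through `read_edf_channel()` + `parse_hypnogram()` +
`segment_epochs()`; class imbalance is handled by `balance_classes()`
(random over-/under-sampling); `run_experiment()` orchestrates the whole
flow from an `experiment_config()` or a YAML file, and
`inst/cli/sleepwave.R` exposes `design` / `simulate` / `run` subcommands
from a shell.

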