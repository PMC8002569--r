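---
title: "Methods: optimal halfband wavelet filter banks for six-stage sleep EEG scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal halfband wavelet filter banks for six-stage sleep EEG scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepwave)
```

## The problem

Overnight sleep is scored on 30-second EEG epochs into six classes under the
R&K convention: wake (W), the four NREM sub-stages S1–S4, and REM. Each stage
has a characteristic spectral signature — alpha/beta-dominant wake, theta in
S1 and REM, sigma-band spindles in S2, increasingly dominant high-amplitude
delta in S3/S4. `sleepwave` implements an automated scoring pipeline that
exploits exactly this structure: each epoch is decomposed into six frequency
sub-bands by a five-level wavelet transform built on a purpose-designed
biorthogonal filter bank, the l1/l2/l∞ norms of the sub-band coefficients
form an 18-feature vector per channel (36 for the dual-channel combination
F4-C4 + C4-A1), and an ensemble of bagged CART trees classifies the six
stages under repeated stratified 10-fold cross-validation.

## Filter-bank design

The analysis lowpass filter `h0` is a linear-phase **halfband** filter of odd
length $L$: its center tap is $1/2$ and every even-offset tap is exactly
zero, so its zero-phase amplitude is

$$A(\omega) = \tfrac12 + 2\sum_{k=1}^{K} a_k \cos((2k-1)\omega),$$

which satisfies $A(\omega) + A(\pi-\omega) = 1$ identically. Two practical
consequences: half the multiplications of a general filter of the same
length, and a passband error that equals the stopband error, so a single
stopband quadratic form covers both. The free taps $a_k$ minimize

$$J(a) = \alpha\, E_s(a) + \gamma\,\bigl(D_t(a) + D_\omega(a)\bigr),$$

where $E_s = \int_{\pi-\omega_p}^{\pi} A(\omega)^2\,d\omega$ is the stopband
energy (assembled from closed-form cosine integrals),
$D_t = 2\sum_k (2k-1)^2 a_k^2$ penalizes time dispersion of the taps, and
$D_\omega = \int_0^\pi \omega^2 A(\omega)^2\,d\omega$ (trapezoid quadrature
on 4096 intervals) penalizes frequency spread. $R$ regularity constraints
force $A$ and its derivatives through order $2R-1$ to vanish at $\pi$;
odd-order derivatives vanish automatically for this parameterization, so the
constraints are $\sum_k a_k = 1/4$ and $\sum_k (2k-1)^{2r} a_k = 0$ for
$r < R$. Because the center tap is fixed the objective has a linear term,
and the design problem is an equality-constrained convex quadratic program,
solved exactly in the constraint null space (this is the eigenfilter idea —
a quadratic form in the taps — in its QP incarnation). Spending all freedom
on regularity ($R = K$) reproduces the classical maxflat halfband filters:
for $L = 7$, exactly $[-1, 0, 9, 16, 9, 0, -1]/32$.

The synthesis lowpass `f0` (odd length $M$, symmetric, *not* halfband) is
designed under the same objective subject to (a) perfect reconstruction —
the product $p = h_0 * f_0$ must itself be halfband about its center,
$p[d] = 1$, $p[d \pm 2k] = 0$ — and (b) $V$ vanishing moments
$\sum_n (-1)^n n^j f_0[n] = 0$, $j < V$. For symmetric filters the odd-order
moment conditions follow from the even-order ones, so $V$ costs
$\lceil V/2 \rceil$ independent constraints. A rank analysis of the PR
system shows feasibility requires $L + M \equiv 0 \pmod 4$, and with
$V \ge 1$ additionally $M \ge L + 2$, the residual design freedom being
$(M - L + 2)/4 - \lceil V/2\rceil$ dimensions. The package defaults —
$L = 11$, $M = 17$, $\omega_p = 0.4\pi$, $\alpha = 0.95$, $\gamma = 0.05$,
$R = 2$, $V = 2$ — leave one free dimension for the objective while keeping
both filters short; all are configuration. The constraint matrix is
rank-checked and an infeasible request (e.g. $M$ too short for the requested
moments) is rejected with a report rather than silently relaxed.

The highpass pair is completed by modulation, $H_1(z) = z F_0(-z)$ and
$F_1(z) = z^{-1} H_0(-z)$, which cancels aliasing; with the halfband product
normalized to $p[d] = 1$ the one-level analysis–synthesis cascade is the
identity with no delay. `make_filter_bank()` verifies this on a random probe
and refuses to return a bank whose roundtrip error exceeds $10^{-8}$.

## Wavelet transform

`wavedec()` iterates the two-channel split five times on the approximation,
yielding six sub-bands Sb-1…Sb-6 ordered coarsest first: at 512 Hz, Sb-1 is
the level-5 approximation (0–8 Hz, delta/theta — maximal in deep sleep),
Sb-2 the level-5 detail (8–16 Hz), up to Sb-6 (128–256 Hz). Boundary
handling is **periodic**: a 30-s epoch at 512 Hz has 15,360 samples,
divisible by $2^5$, so every level halves exactly (480, 480, 960, 1920,
3840, 7680 coefficients) and perfect reconstruction holds to machine
precision with no bookkeeping exceptions. Epochs are three orders of
magnitude longer than the filters, so the extension choice is immaterial to
the features. Decimation keeps even-indexed samples of the full-rate
output; the phase convention is pinned by the reconstruction self-test, not
by assumption.

## Features, balancing, classifier

Each sub-band contributes its l1 norm, l2 norm and peak absolute value
(l∞): 18 features per channel, concatenated to 36 for two channels. No
scaling or selection follows — trees are scale-invariant and the ANOVA
screening (below) shows all features separate the classes strongly.

Sleep data are inherently imbalanced (S1 is typically only a few percent of
epochs). `balance_classes()` equalizes counts at a target per class:
under-sampling draws without replacement, over-sampling keeps every
original and duplicates uniform draws with replacement — resampling only,
never synthetic interpolation. The default protocol balances the **whole
dataset before cross-validation**, which reproduces the published balanced
epoch totals; the documented caveat is that duplicated epochs can then span
train and test folds, inflating apparent accuracy. A `strict` mode that
balances only within training folds is provided for honest generalization
estimates, but it is not the reference protocol.

The classifier is an ensemble of bagged CART trees: Gini impurity,
best-first growth with thresholds at midpoints of consecutive distinct
values, a cap on the number of splits, full-size bootstrap per tree, and no
feature subsampling (bagging, not a random forest). Equal-gain ties resolve
to the lowest feature index then lowest threshold, and all randomness is
confined to the bootstrap draws, so fits are reproducible from the seed.
Predictions average per-tree leaf class distributions; ties in the argmax go
to the earliest class in (W, S1, S2, S3, S4, REM). A `learning_rate`
configuration field is accepted for interface parity and ignored — it is a
boosting parameter with no meaning for bagging, and the package says so at
fit time rather than pretending otherwise. `tune_bagged()` sweeps ensemble
size and split cap by k-fold CV and returns the error surface plus the
argmin (ties toward the smaller model).

## Evaluation conventions

`repeated_cv()` runs stratified 10-fold CV (per-class round-robin
assignment keeps fold proportions within one sample — without
stratification a 4% class could miss a fold entirely) repeated five times by
default. Three conventions are worth making explicit:

* **Trial aggregation uses the population (divide-by-n) standard
  deviation.** The five published healthy trial accuracies (76.26, 77.66,
  79.06, 79.66, 78.86) aggregate to 78.3 ± 1.21 only under the
  divide-by-n convention; the sample convention gives 1.35.
* **Per-class "individual accuracy" is one-vs-rest accuracy**, i.e.
  $(TP + TN)/N$ after collapsing the 6×6 matrix to class-versus-rest. This
  is the reading under which the published per-stage figures (e.g. 95.84%
  for W on the healthy subset) are reproducible from the published
  confusion table, whose diagonal entry for W is only 68.8%.
* **The kappa error is the population standard deviation of per-trial
  kappa**, parallel to the accuracy aggregation.

Cohen's kappa uses the standard marginal-product chance correction; with
exactly uniform true-class counts the chance agreement is exactly $1/6$.
ROC analysis is one-vs-rest per class with trapezoid AUC (cross-checked
against pROC in the tests).

## Synthetic cohorts

The generator exists so that every downstream stage is testable without the
CAP sleep database. Each stage has a spectral profile over the six classical
EEG bands and a target RMS amplitude; an epoch is band-limited Gaussian
noise synthesized in the frequency domain with band powers proportional to
the profile weights, scaled to the stage RMS. The defaults follow textbook
physiology (wake: alpha/beta, low amplitude; S1: theta; S2: theta + sigma;
S3: 60% delta; S4: 85% delta, largest amplitude; REM: mixed theta/beta,
low amplitude) and give strictly ordered delta power S4 > S3 > S2 > REM and
a coarse-band l1 norm maximal in S4 — the qualitative pattern of the
published feature tables. The unipolar channel C4-A1 is synthesized at
twice the bipolar amplitude, mirroring the published norm magnitudes.
Per-epoch noise streams are derived by hashing (master seed, group, stage,
epoch index, channel), so cohorts are reproducible and order-independent.

What the generator does **not** emulate: transient events (spindle bursts as
discrete events, K-complexes, eye movements, artifacts), stage-transition
dynamics, inter-subject variability, or disorder pathophysiology. Its
stationary spectra with fixed per-stage RMS make the six classes far more
separable than real sleep EEG — the synthetic-cohort pipeline recovery test
(600 epochs, 100 per stage, at 512 Hz) sits at ceiling accuracy. Passing it
therefore validates the *plumbing and the mathematics* (design →
decomposition → features → classifier → metrics), not clinical performance;
the published CAP-database accuracies are not reproducible without the
database itself and are deliberately outside the test surface.

## Numerical choices and degenerate inputs

Structural halfband zeros are imposed by construction, never left to the
optimizer, so `verify_halfband()` returns exactly 0 for every design. The
QP is solved via an SVD minimum-norm particular solution plus a QR null
space basis; the reduced Hessian is positive definite for any positive
objective weight. Empty coefficient vectors return norm 0 with a message;
zero signals propagate to all-zero sub-bands and features; a class absent
from balancing input, a class with fewer members than folds, and band-length
mismatches in reconstruction are all hard errors with actionable messages.
EDF export uses integer physical bounds so the 16-bit roundtrip error stays
within one quantization step.

Problem sizes in the test suite are chosen for a desk-scale run: most
fixtures use 128 Hz cohorts of 10–50 epochs per stage; the acceptance
checks use the full 512 Hz epoch length (15,360 samples) with 100 epochs
per stage and 100-epoch PR sweeps. The whole suite runs in well under a
minute on one core.

## Known limitations

* The reference protocol balances before cross-validation (see caveat
  above); `strict` mode exists but changes the numbers.
* Published sources for this task family contain internal inconsistencies
  (e.g. an S2 share printed as 35.50% where the row counts give 35.49%, and
  a healthy-subset accuracy appearing as both 78.3% and 78.8%); the package
  reproduces what the arithmetic supports and does not arbitrate.
* AASM five-stage scoring (merging S3/S4 into N3) is a trivial relabeling
  left to the user; the pipeline is six-class throughout.
* EDF+ embedded annotations and CAP A-phase scoring are out of scope; the
  hypnogram reader targets plain-text scorer exports.
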