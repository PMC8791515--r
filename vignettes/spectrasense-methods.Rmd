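---
title: "Methods: models, preprocessing, and the committee sensitivity analysis"
author: "spectrasense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, preprocessing, and the committee sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spectrasense classifies mid-infrared (ATR-FTIR) absorbance spectra of tissue
samples as benign or malignant and scores each wavenumber's diagnostic
importance with a neural-network-committee perturbation analysis. This
vignette explains the models and procedures, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic-data
tests demonstrate.

## Data model

A dataset is a matrix of `N` spectra over a common wavenumber grid, stored
high to low in cm^-1 (the conventional plotting direction), with one binary
diagnosis label per sample. The default working window is the fingerprint
region, 1800–850 cm^-1 at 2 cm^-1 steps (476 channels), where the
biomolecule-specific absorption bands of proteins, lipids, nucleic acids and
carbohydrates live. The canonical on-disk form is a wide CSV (one
`wavenumber_cm1` column, one column per sample) plus a `labels.csv`
companion; JCAMP-DX files with uncompressed `X++(Y..Y)` tables are read-only
input.

## Preprocessing

Three per-spectrum steps, each optional and re-orderable via
`preprocess_config()`:

1. **Z-score normalisation.** Every spectrum is centred to mean 0 and scaled
   to unit sample standard deviation (N−1 denominator). This removes
   per-sample intensity scale (contact pressure, section thickness) and is
   affine-invariant: `znormalize(a*x + b) == znormalize(x)` for `a > 0`.
   A constant spectrum has no scale and raises an error.
2. **Rubber-band baseline correction.** The baseline is the lower convex
   hull of the (wavenumber, absorbance) points, built from 64 evenly spaced
   anchor candidates (endpoints always included), linearly interpolated, and
   subtracted. A straight line is its own hull, so affine drifts vanish
   exactly; the corrected endpoints are 0. The hull is the standard reading
   of "rubber band" correction; the anchor count is configurable.
3. **Fingerprint cropping.** Channels with `850 <= wavenumber <= 1800`
   (closed interval) are retained.

The default order is normalise, baseline-correct, crop. Normalise-last is
more common in chemometrics and is available by reordering; the package
treats the order as a configuration choice, and a regression test documents
that the two orders do not commute. The channel count is always derived from
the data, never hard-coded.

## Principal component analysis

`fit_pca()` computes the top two eigenvectors of the unnormalised scatter
matrix `t(X - Xbar) %*% (X - Xbar)` via SVD. Explained fractions are
eigenvalues over the trace, so the missing `1/(N-1)` factor is immaterial.
Eigenvector sign is fixed by making each component's largest-magnitude
loading positive, which keeps tests and plots reproducible. Scores are
`(X - Xbar) %*% [s1, s2]`; `biplot_table()` exports scores and loadings for
plotting.

## Feed-forward networks

`train_fnn()` trains fully connected networks with:

* `n_hidden_layers` hidden layers (reference designs use 2, 4 or 8) of
  constant `width` (reference widths 350/400/300; examples here use 8–30 so
  they run in seconds);
* SELU activations (λ ≈ 1.0507, α ≈ 1.6733) in the hidden layers and a
  2-node softmax output;
* binary cross-entropy on the malignant output probability, clamped at
  1e-12 — for a two-class softmax this equals categorical cross-entropy;
* Gaussian weight initialisation with per-layer SD `1/fan_in` and zero
  biases. The `1/fan_in` figure is taken literally as an SD (not the
  `1/sqrt(fan_in)` LeCun variance rule); with SELU the forward signal then
  shrinks layer to layer, which slows early training but remains trainable
  at the widths used here;
* alpha-dropout after every hidden layer with keep probability 0.9.
  A "90% SELU dropout" specification is read as keep = 0.9: a 90% drop
  *rate* would destroy training, and the SELU literature recommends small
  drop rates with the alpha-dropout form, which preserves the
  self-normalising property by replacing dropped units with the SELU
  saturation value and applying an affine correction;
* per-sample (batch size 1) AdaGrad SGD with seeded shuffling:
  `G += g^2; w -= lr * g / (sqrt(G) + 1e-8)`, accumulators starting at 0.

Everything downstream of `set.seed()` — initialisation, shuffling, dropout
masks — flows through R's RNG, so a configuration plus a seed reproduces a
model bit for bit. The training loop is compiled (RcppArmadillo); analytic
gradients are verified against central finite differences to 1e-5 relative
error in the test suite.

The optimisation grids are fixed closed forms: ten learning rates generated
by halving and fifthing alternately from 1 down to 5e-5, and twenty widths
from 10 to 462. `grid_search_fnn()` averages final validation accuracy over
stratified Monte-Carlo splits for every pair and returns the argmax.

## Benchmark classifiers

All six are implemented in the package, not wrapped from other libraries,
because their exact construction (including their probability outputs) is
part of the method being reproduced. Established implementations are used
only as independent cross-checks in the tests.

* **LDA.** PCA to two scores, then the Fisher direction
  `w = Sw^-1 (mu_B - mu_M)` (ridge 1e-9 when the within-class scatter is
  singular). One normal distribution per class is fitted on the projections
  and prediction is the softmax of the two class densities. Softmax of raw
  densities (not log-densities) is kept deliberately: it reproduces the
  referenced construction, and thresholding at 0.5 is unaffected because
  softmax preserves the density order.
* **Linear SVM.** Saddle-point SGD on the hard-margin Lagrangian with
  benign = −1, malignant = +1. Each visit updates the sample's multiplier
  by its exact Lagrangian gradient `lr * (1 - margin)`, clipped at 0, and
  the primal variables by `dL/dw = w - sum(alpha*y*x)` and
  `dL/db = -sum(alpha*y)`. Saddle-point SGD orbits the optimum rather than
  converging, so the returned parameters are Polyak averages over the second
  half of training; on a 1-D separable toy this lands on the exact KKT
  point (unit margins, interior multipliers exactly 0). Probabilities come
  from Platt scaling — a sigmoid over decision values fitted by Newton
  iteration with the standard smoothed targets — on the validation set when
  one is supplied.
* **Logistic regression.** Plain per-sample SGD on the binary
  cross-entropy of `p = plogis(b + w.x)`, overflow-safe.
* **CART.** Binary splits minimising the weighted Gini impurity of the two
  children over midpoint thresholds, ties to the smallest threshold. The
  frontier deepens one level at a time and growth stops as soon as
  validation accuracy drops, reverting the last level. A printed
  "diversity index" form that is in fact a purity (its minimisation would
  select maximally impure splits) is retained behind `literal = TRUE` for
  comparison, with the standard impurity as the default.
* **Random forest.** Row bootstrap only (no feature subsampling), majority
  vote with ties resolved toward malignant — the conservative choice for a
  screening tool. `rf_size_search()` scans 3–100 trees on mean validation
  accuracy.
* **Naive Bayes.** Each channel is binarised at its best Gini threshold;
  channels enter in ascending impurity order starting from the three
  purest, stopping when validation accuracy decreases. The default
  prediction is the add-one-smoothed posterior with class priors; the
  prior-free likelihood-ratio form is retained behind `literal = TRUE`
  because without priors an uninformative model degenerates to certainty.

## Evaluation protocol

A "10-fold over 50 trials" protocol with 70/15/15 train/validation/test
proportions cannot be a partition-based k-fold; it is implemented as
Monte-Carlo cross-validation: for each of `trials x folds` cells the three
sets are independently redrawn at random, stratified so each set's class
ratio is within one sample of the global ratio (largest-remainder allocation
per class). Six metrics are computed per test set with malignant as the
positive class: trapezoidal ROC AUC over all distinct score thresholds,
accuracy, PPV, NPV, specificity (SR) and recall (RR), thresholding
`p_malignant > 0.5`. Metrics with zero denominators are flagged undefined,
excluded pairwise and counted. Aggregation follows the
trial-then-fold structure: the overall mean is the mean over trials of the
per-trial fold-means (equal to the grand mean on a complete grid), and the
overall SD is the mean over trials of the per-trial fold sample SDs — the
literal published aggregation, not the pooled SD.

Model comparisons use a native two-sided Mann-Whitney U test: exact
enumeration of the permutation distribution when both samples have at most
8 values, and the tie-corrected normal approximation with continuity
correction otherwise. The exact mode is cross-checked against brute-force
pair counting and `wilcox.test` in the suite. Shapiro-Wilk normality checks
in `peak_table()` delegate to `stats::shapiro.test`.

## Committee sensitivity analysis

The importance of channel `j` to a trained network is probed by adding a
perturbation `Δx = f * mean(x_j)` — `f` from −50% to +50% in 5% steps, 21
values including 0 — to channel `j` of every sample in the network's own
70% balanced experiment set, and recording the squared deviation of the
softmax outputs from the ideal one-hot targets, halved and averaged over
samples so the response lies in [0, 1]. (A printed difference-of-squares
variant of the response is available behind `literal = TRUE`; it is not
bounded and is not the default because the bounded reading is the one
consistent with responses being probabilities.) The per-channel response is
the mean over the 21 steps, and the committee profile is the average over
`committee_size` networks (reference size 50) that differ only in seed and
experiment-set draw. Networks are evaluated in inference mode — dropout off —
so the sweep is deterministic given the seed. The sweep exploits the fact
that perturbing one input channel changes the first-layer pre-activations by
a rank-1 update, which makes the full 476 x 21 sweep of a committee member a
sub-second operation.

`significant_regions()` turns a profile into contiguous wavenumber
intervals above a threshold (mean + 1 SD, or a top-quantile rule).

### What the committee response does and does not measure

Two structural properties matter when reading a profile. First, the
perturbation is *proportional to the channel mean*, so channels with large
mean absorbance receive proportionally larger absolute perturbations and
everything else equal show larger responses; channels whose mean is near
zero are nearly invisible to the probe. Second, per-sample AdaGrad
normalises each parameter's update by its own gradient history, so weight
*magnitudes* grow at similar rates on informative and uninformative input
channels; after substantial training the response profile therefore tracks
the squared mean spectrum more than the class-informative channels. On
simulated data whose discriminative bands sit at mid-to-low normalized
absorbance, the package's own experiments show the top responses landing on
the largest non-discriminative bands, with the planted and non-planted
channel means equal to three significant digits. The committee analysis is
validated end to end on data whose discriminative band dominates the mean
spectrum (top-decile recovery 1.0); on data where it does not, the profile
should be read as "where the network's output is most perturbable", not as
a ranking of diagnostic channels. This is an inherent property of
mean-scaled input perturbation combined with AdaGrad, and it is surfaced
honestly by the acceptance checks rather than hidden.

## Synthetic data generator

`simulate_dataset()` emulates fingerprint spectra of FFPE breast tissue:
ten Gaussian bands (SD 8 cm^-1, a typical mid-IR bandwidth) at the
characteristic peak positions, with class-conditional amplitude means and
SDs on the normalized-absorbance scale taken from published per-peak
statistics of such spectra; exactly five bands (1452, 1399, 1337, 1279,
1236 cm^-1 — lipids, nucleic acids, phospholipids) differ between classes.
Because raw absorbance bands are positive peaks — a "negative" normalized
amplitude only means a peak weaker than the spectrum mean — every drawn
amplitude rides on a `band_floor` pedestal (default 3.5, clearing the most
negative tabulated draw by about 3 SD). Per-sample nuisance: a random
quadratic baseline drift, a log-normal gain, an additive offset and white
noise (SD 0.02), so all three preprocessing steps do real work.
`default_bands(separation = s)` rescales the discriminative bands' SDs so
the standardised class gap is exactly `s`, defining reproducible difficulty
levels. `ground_truth_mask()` marks the channels within a chosen number of
band SDs of any discriminative center.

The generator does **not** emulate Mie scattering artifacts, paraffin
residue, per-scan noise structure, wavenumber calibration error, or
correlated band amplitudes (each band's amplitude is drawn independently).
Passing tests on this generator therefore demonstrate correctness of the
algorithms and pipelines, not clinical performance on real tissue spectra.

## Problem sizes and runtime choices

The reference protocol (50 trials x 10 folds, committee of 50, 1000 epochs,
widths 300–400) is available through the same functions but is not what the
test suite runs. The suite and the acceptance script use scaled study
conditions chosen to finish on a laptop CPU: n = 200 simulated spectra
(100/100), 5 trials x 3 folds, 200 epochs, width 30, committees of 10.
These sizes were fixed once as the package's desk-scale conditions; the
statistical structure (stratification, aggregation, seeding) is identical
at both scales.

## Numerical choices

* BCE clamp 1e-12; AdaGrad epsilon 1e-8; LDA scatter ridge 1e-9.
* Gini ties break toward the smallest threshold; forest vote ties toward
  malignant; the classification threshold is strictly `p > 0.5`.
* Rubber-band hull uses Andrew's monotone chain on ascending wavenumber;
  anchors are `round(seq(1, L, length.out = n_points))` deduplicated.
* CSV output prints 17 significant digits, so write/read round trips are
  exact to double precision.
* All random draws go through R's RNG; derived seeds stay far below 2^31.
* Degenerate inputs error loudly (constant spectrum, single-class training
  set, empty crop window, off-grid peak positions) rather than returning
  silent defaults.

## Known limitations

* LDA reduces to two principal components before Fisher's criterion, so
  when the dominant variance directions carry no class signal its accuracy
  is capped regardless of the separability of the full spectra — visible in
  this package on configurations with a high-variance non-discriminative
  band, and consistent with LDA being the weakest model of this family on
  real tissue spectra.
* The committee sensitivity profile inherits the mean-scaling and AdaGrad
  confounds described above.
* The SVM is hard-margin; heavily overlapping classes rely on the averaged
  iterates rather than a soft-margin C parameter.
* Probabilities from the literal naive-Bayes ratio and the literal
  difference-of-squares response are intentionally uncalibrated; they exist
  for comparison with their published printed forms.
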