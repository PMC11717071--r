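---
title: "Hyperspectral analyte calibration: models, selection and tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral analyte calibration: models, selection and tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`specalib` implements a complete chemometric calibration pipeline for
predicting a scalar analyte (the motivating case is protein content of
milk powder, in g/100 g) from visible/near-infrared hyperspectral
reflectance spectra: reflectance correction, spectral preprocessing,
wavelength selection by the CARS-UVE cascade, a bidirectional recurrent
network with attention pooling as the regressor, whale-optimization
hyperparameter search, and the standard calibration metrics. This
vignette explains each component, the assumptions behind it, and the
choices made where the design was genuinely open.

## The data model

A `spectral_dataset` couples an `n x p` reflectance matrix (rows are
measured spectra; columns are wavelengths, by default 125 bands spanning
400-1000 nm) with one reference analyte value per row, a brand label and
a sample id. Reflectance is assumed dark/white corrected,

$$I_c = \frac{I_r - I_b}{I_w - I_b},$$

which `black_white_correct()` applies elementwise, refusing (rather than
clipping) bands where the white and dark references coincide: a zero
denominator means the sensor saw no dynamic range there, and silently
patched values would poison downstream band selection.

## The synthetic generator

The real milk-powder spectra behind the motivating study are not public,
so the package ships a generator whose defaults emulate that study's
design: 5 brands x 20 samples x 8 regions of interest = 800 spectra,
with brand-level protein values 19.0, 23.8, 28.0, 25.4 and 20.2 g/100 g.
Each spectrum is

* a smooth brand-independent base curve (sigmoidal rise through the
  visible range with a fixed dip near 760 nm),
* minus Gaussian absorption bands whose depths are proportional to the
  sample's analyte value — four bands in the 900-1000 nm overtone region
  plus broad visible bands near 450 and 670 nm,
* plus a low-order polynomial baseline drift per sample
  (sd 0.01 reflectance units on the constant term),
* plus band-wise per-sample noise (sd 0.001) shared by the sample's ROIs,
* plus i.i.d. per-ROI measurement noise (sd 0.002).

Per-sample analyte jitter (sd 0.1 g/100 g) creates within-brand variance,
since the study reports a single wet-chemistry value per brand. Repeat
acquisitions of the same physical sample (the study mentions three image
captures per product but selects one clear image) are not modeled; the
ROI level is the only within-sample replication. The
noise magnitudes were chosen once as representative of ROI-averaged
reflectance data, where per-band noise well below 1% of full scale is
typical; they are parameters of `synthetic_spec()`, not tuned values.

What the generator deliberately does **not** emulate: nonlinear
analyte-absorbance relationships (Beer-Lambert saturation), scatter
effects that would call for MSC/SNV correction, wavelength-dependent
noise, or instrument drift between acquisition sessions. Passing the
package's tests therefore demonstrates that the pipeline recovers a
linear-in-depth signal under realistic noise — it does not certify
performance on real instrument data, where preprocessing choices matter
more.

The generator's signal is linear in the analyte, which is why the linear
baselines (PLSR) are essentially exact on noiseless draws and remain
strong on the defaults; the network comparison on synthetic data is
therefore about matching, not beating, the linear bound.

## Preprocessing chains

Six operators are provided — mean centering (MC), standardization (SS),
min-max scaling (MMS), Savitzky-Golay smoothing (SG) and first/second
derivatives (D1/D2) — composable in any order, mirroring the fourteen
single and chained variants the motivating study compares before
settling on mean centering. Two conventions are fixed here:

* Scaling statistics are **column-wise** (per wavelength), the standard
  chemometric convention, and are learned from the calibration matrix
  only; `apply_chain()` reuses them on test spectra, never refits.
* Derivatives default to the Savitzky-Golay filter (window 11, order 2 —
  common near-infrared practice; the study does not state its values)
  so the band count is preserved; a finite-difference mode is available
  and shrinks the grid by the derivative order.
* Chained names apply left to right: `list("SS", "SG")` standardizes,
  then smooths.

## PLS1 and cross-validation

The selection machinery scores subsets with a single-response NIPALS
PLS. For one response the weight extraction is closed-form, and at full
rank the fit coincides with least squares (a property the tests exploit
as an independent oracle). `rmsecv()` reports the k-fold
root-mean-square error of cross-validation, aggregating all held-out
predictions into one RMSE; folds are contiguous blocks of a seeded
shuffle, 10 folds by default as in the study. The latent dimension is
never fixed a priori: CARS and UVE scan 1-10 components and use the
RMSECV minimizer, treating the dimension as a nuisance parameter (the
study never reports its value).

## Wavelength selection: CARS, UVE, and the cascade

**CARS** runs 50 Monte Carlo sampling rounds (the study's setting). Each
round fits a PLS model on a random 80% row subsample restricted to the
currently retained bands, forces the retention count down an
exponentially decreasing schedule ($r_i = a e^{-ki}$ with $a, k$ solved
so the first round keeps all $p$ bands and the last keeps 2), keeps the
top bands by absolute regression coefficient, resamples among them with
probability proportional to that coefficient, and records the subset's
RMSECV. The final selection is the subset of the minimum-RMSECV round.
The 0.8 subsample ratio and the schedule constants follow standard CARS
practice; the study cites but does not restate them.

**UVE** appends one tiny-amplitude (1e-10 of the data scale) Gaussian
noise band per real band, refits the PLS model across resampling splits
(leave-one-out up to n = 200, otherwise twenty 20%-deletion splits),
and scores every band by coefficient stability — mean over splits
divided by sd. The cutoff is the maximum absolute noise-band stability
(times a configurable factor, default 1), so appended noise bands are
excluded by construction. One implementation subtlety: the internal
random stream is decoupled from the user-facing seed by a fixed linear
scramble. Without it, a user who generates data under `set.seed(s)` and
selects with `seed = s` would hand the noise bands the exact normal
draws the data were built from, making each noise band a scaled copy of
a real band and voiding the cutoff.

The **CU cascade** applies UVE to the CARS-selected columns and reports
indices in the original band coordinates, so the result is always a
subset of the CARS selection — the study reduces 125 bands to roughly
half by CARS and then to 53 by UVE on its (non-public) data. Pipeline
order here is preprocess, then CARS, then UVE; the study leaves the
order of preprocessing relative to selection implicit.

## The recurrent calibration model

The regressor treats the (selected) spectrum as an ordered sequence —
one reflectance value per wavelength, increasing order. This sequencing
of the wavelength axis is the central architectural assumption: neighbor
bands are strongly correlated, and recurrence exploits that the same way
it exploits temporal order in a time series. The architecture is

1. two stacked LSTM layers, each run forward and backward over the
   sequence (per-direction hidden sizes `hidden1`, `hidden2`);
2. at every step, a tanh-weighted merge of the two directional states,
   $O_t = \tanh(W_{\vec h} \vec h_t + W_{\overleftarrow h}
   \overleftarrow h_t + b)$;
3. additive attention over steps: each merged state is projected through
   a tanh layer of width `attn_dim` and scored by a learned vector, the
   scores are softmax-normalized, and the context vector is the
   attention-weighted sum of merged states;
4. a tanh dense layer (width `dense`) and a linear output.

Attention consumes the post-merge states (the pre/post choice is not
pinned down in the motivating description; post-merge is the natural
reading of "weighting the hidden states"). The attention form is
additive; with `attention = FALSE` the pooling is uniform, and
`model_type = "lstm"` drops the backward streams, giving the plain-LSTM
and BiLSTM comparison variants. Targets are standardized to zero
mean/unit sd from the training responses before optimization — the
reported loss curves are on that scale, predictions are de-standardized
by default, and `metrics_report()` records which scale a row uses.
Training uses Adam (the study does not name its optimizer) on
minibatches; forward and backward passes (full backpropagation through
time) are compiled code, verified against central finite differences to
1e-4 relative error in the test suite.

Initialization is Glorot-uniform with forget-gate biases at 1,
deterministic in the config seed. Training aborts with a diagnostic on a
non-finite loss rather than returning a silently broken model; during
hyperparameter search such candidates score `+Inf` and the search
continues.

## Whale optimization

`woa_minimize()` is a faithful bounded implementation of the whale
optimization algorithm: encircling moves toward the best-known position,
logarithmic-spiral "bubble-net" moves around it, and randomized search
toward a random whale while the shrinking coefficient still permits
exploration ($a$ decays linearly from 2 to 0; $A = 2ar_1 - a$,
$C = 2r_2$). The coefficient draws are per-dimension vectors; the
explore/exploit branch uses the mean of $|A|$, which reduces to the
canonical scalar rule when the dimension is 1. Positions are clamped to
the box after every move, and the best-so-far curve is monotone by
construction. Two published ambiguities are resolved explicitly:

* the branch condition printed as "p <= 0.5" on both arms is read as the
  canonical rule (p < 0.5 encircle/search, p >= 0.5 spiral);
* the reported tuned learning rate (0.00829) lies below the stated
  search bound [0.01, 0.1], so the default space searches the learning
  rate on a log10 scale over [1e-3, 1e-1], containing the reported
  optimum; a seventh dimension (attention width, 1-50) is added because
  a tuned value is reported without a bound. Both are removable.

`tune_network()` decodes each whale position into a network config
(integers rounded half-up then clamped; motion stays in the relaxed
space, standard metaheuristic practice), trains the network, and returns
the validation MSE (standardized scale) as fitness. The default swarm is
10 whales (the study gives 10 iterations but no swarm size); the
acceptance-scale search uses 6 whales x 5 iterations, which already
dominates the untuned default configuration on the synthetic defaults.

## Metrics and reporting

`metrics_report()` returns the chemometric quadruple — calibration
R2/RMSE ("RC2"/"RMSEC") and prediction R2/RMSE ("RP2"/"RMSEP") — plus
the relative percent deviation. RPD is reported from held-out
predictions through the identity RPD = sd(y)/RMSEP, which equals
$1/\sqrt{1 - R_P^2}$ at full precision; applying the latter to *rounded*
printed R2 values does not reproduce printed RPDs, so the identity form
is the reliable one. `percent_change()` and `compare_report()` reproduce
the increase/decrease arithmetic used in published model comparisons.
Reported decimals follow the field's four-significant-figure style.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the full study-scale
synthetic problem: 800 x 125 spectra, a 7:3 stratified split, a
validation fifth carved from the training set, 50-round CARS with
10-fold RMSECV, and a 6-whale x 5-iteration hyperparameter search
(roughly 36 trained candidate networks). Search candidates — and the
untuned reference they are compared against — are scored after training
on a random half of the calibration split, a standard economy for
hyperparameter search; the final model is trained on the full split.
Property suites use smaller matrices (for example 120 x 100 for
selection-recovery benchmarks and 20-seed medians for stochastic
checks). Degenerate inputs fail loudly
and early: constant responses, constant columns under SS/MMS, band-count
mismatches between a fitted chain or model and new data, and unfitted
objects all raise errors naming the offending band or row. Ties in the
CARS forced selection are broken by column order; RMSECV fold
assignments derive from one seeded shuffle and are reproducible.

## Known limitations

* The generator's linear signal means synthetic benchmarks cannot
  demonstrate the nonlinear-regime advantages a recurrent model may have
  on real spectra.
* CARS on strongly collinear, high-SNR synthetic spectra often finds the
  full-band model competitive (its RMSECV minimum can sit in an early
  round); the UVE stage then does most of the pruning. On real noisy
  data the schedule's later rounds matter more.
* The whale search trains each candidate once; fitness noise from
  initialization is not averaged out. With small swarms this makes the
  search a strong but not exhaustive baseline-beater.
* Checkpoints serialize parameters as JSON text (17 significant digits,
  bit-exact on IEEE doubles); they are portable but not compact.
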