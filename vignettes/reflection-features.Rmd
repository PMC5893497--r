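---
title: "Reflection-coefficient features for mental-task EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflection-coefficient features for mental-task EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eegreflect)
```

## The problem and the model

Mental-task brain–computer interfaces must decide, from a short stretch of
multichannel scalp EEG, which of several cognitive tasks (mental
multiplication, visual counting, letter composing, rest, figure rotation) a
subject is performing. A short EEG frame is modeled as the output of a
causal, stable, linear time-invariant autoregressive (AR) system driven by
white Gaussian noise:

$$x(n) = -\sum_{k=1}^{p} a_k\, x(n-k) + u(n), \qquad u(n) \sim
\mathcal{N}(0, \sigma_u^2).$$

Classical AR-parameter features inherit two problems: the $a_k$ are
unbounded, and estimating them involves solving a linear system per frame.
This package instead uses the **reflection coefficients** $k_1, \dots,
k_p$: the lag-$m$ partial autocorrelations of the frame, obtained directly
from the biased sample autocorrelation

$$r_x(m) = \frac{1}{N}\sum_{n=0}^{N-1-m} x(n)\,x(n+m)$$

by the Levinson–Durbin recursion

$$k_m = \frac{r_x(m) - \sum_{j=1}^{m-1} d_j^{(m-1)} r_x(m-j)}{E^{(m-1)}},
\qquad
d_j^{(m)} = d_j^{(m-1)} - k_m d_{m-j}^{(m-1)},\quad d_m^{(m)} = k_m,$$

with residual energies $E^{(m)} = (1-k_m^2)E^{(m-1)}$, $E^{(0)} = r_x(0)$.
No matrix inversion is needed, every $|k_m| < 1$ for a stable system (a
bounded feature), and raising the order from $p$ to $p+1$ changes only the
newest coefficient, so the features are insensitive to the model-order
choice. Two coefficients per channel suffice in practice; on the standard
six-electrode montage (C3, P3, O1 left; C4, P4, O2 right) that is a
12-dimensional feature vector per frame, against 60–90 for the band-power
baselines.

The divisor-$N$ (biased) autocorrelation estimator is used deliberately at
every lag: it makes the estimated sequence positive semidefinite, which is
what guarantees $|k_m| \le 1$ and nonincreasing residual energies. The
unbiased $1/(N-m)$ variant offers no such guarantee and is not provided.

## Pipeline and tunable parameters

The processing order is notch → normalize → frame → features → classifier.

* **Notch filter** (`notch_filter`): second-order constant-gain IIR notch,
  default 60 Hz, quality factor $Q = 30$ (bandwidth 2 Hz). Narrow, so the
  40–100 Hz region — which carries usable task information and motivates
  full-band analysis — is untouched.
* **Normalization** (`normalize_recording`): each channel is standardized
  to zero mean, unit variance over the *full session*, before framing, so
  frames carry session-level statistics and band powers are on a common
  scale across sessions.
* **Framing** (`frame_signal`): 1-s frames advanced by 0.5 s (50 %
  overlap), trailing partial frames dropped; a 10-s session at 250 Hz gives
  19 frames of 250 samples. Frames start at the first sample; the step is
  `round(shift * fs)` samples.
* **Feature order** (`extract_reflection_features`): default `n_coeffs =
  2` per channel; columns are channel-major (`C3_k1, C3_k2, P3_k1, ...`).
  The autocorrelation is computed only up to lag `n_coeffs` — the minimal
  computation the recursion needs.
* **Classifier** (`loocv_classify`): soft-margin SVM (solver:
  `e1071::svm()`), default quadratic kernel $(x \cdot x' + 1)^2$ with
  penalty $C = 1$; polynomial default degree 3 with the same $+1$ offset;
  RBF scale $\gamma = 1/(\text{n\_features} \times \text{var}(X))$. These
  hyperparameters are conventional defaults, all exposed through
  `kernel_spec()`. Features enter the kernel unscaled: reflection
  coefficients are already bounded in $(-1,1)$, and after session
  normalization band powers of a frame are $O(1)$, so a common scale is
  built into the features themselves and the kernels stay exactly the
  documented functions of the raw features.

## Evaluation protocol

Accuracy is estimated by frame-level leave-one-out cross-validation: each
frame in turn is predicted by an SVM trained on all remaining frames, and
accuracy is the percentage of correct predictions. With 50 %-overlapping
frames, the held-out frame shares half its samples with two training
frames from the same session, so this protocol is *optimistic* about
generalization to new sessions; it is nevertheless the default because it
is the protocol of record in this literature. `group_by_session = TRUE`
holds out whole sessions instead and is the setting to use when
between-session generalization is the question. Exact margin ties are
resolved toward the lexicographically smaller label for determinism.

The Wilcoxon rank-sum screen (`ranksum_separability`) quantifies
per-feature class separability; principal-component reduction
(`pca_reduce`) projects the centered feature matrix onto its leading
components without rescaling.

## Band-power baselines

`assemble_par_features` implements the PAR4/PAR5/PAR6 comparison families:
per-band periodogram power for every channel plus the asymmetry ratio
$A(i,j) = (P(i)-P(j))/(P(i)+P(j))$ for every left × right electrode pair
and band. Bands: delta 0.1–4 Hz (the lower edge matches a typical
0.1–100 Hz acquisition passband), theta 4–7, alpha 8–13, beta 14–20, gamma
24–37, high 40–100. PAR4 uses the first four, PAR5 adds gamma, PAR6 adds
the high band, giving $N_b \times l + N_b \times N_i \times N_j$ features
= 60 / 75 / 90 on six channels. The power estimator is the raw frame
periodogram summed over in-band bins (edges inclusive): deterministic,
adequate at 250 samples per frame, and power-conserving over a band
partition. The original band-power methods' exact estimators and filters
live in their own publications; no accuracy parity with those
implementations is claimed.

## Numerical choices

* **Zero-phase filtering.** The notch and band-pass stages apply their IIR
  designs by multiplying each channel's DFT by the filter's squared
  magnitude response $|H(e^{j\omega})|^2$ — the net response a
  forward-backward (filtfilt) pass targets — rather than by running the
  recursion over the finite record. The high-$Q$ notch rings for about a
  second; run over a 10-s session, that transient is excited at the data
  edges and contaminates a substantial fraction of the record, whereas the
  frequency-domain application is transient-free and exactly zero-phase.
  The cost is a circular boundary (the ends of the session mix within the
  effective response length), negligible for these narrow filters on
  stochastic signals.
* **Degeneracy.** The recursion stops with an error when
  $E^{(m)} \le 10^{-12}\, r_x(0)$: the frame is then perfectly predictable
  (e.g. a pure sinusoid or an all-zero frame) and reflection coefficients
  beyond that order are numerically meaningless. Errors carry the frame
  and channel.
* **Frame means.** Session-level normalization leaves individual frame
  means near, but not exactly, zero; the autocorrelation is computed on
  the frames as-is, with no per-frame re-centering. Re-centering would
  change the features at $O(1/\sqrt{N})$; not doing so keeps the estimator
  exactly the documented sum.
* **AR simulation.** `simulate_ar_process` discards a 1000-sample burn-in
  so the retained samples are effectively stationary draws; class models
  are specified in reflection space and converted by the exact step-up
  recursion, which guarantees stability by construction. All generators
  derive per-channel and per-session seeds deterministically from one
  master seed and restore the global RNG state afterwards.

## What the synthetic generator does and does not emulate

`simulate_recording` reproduces the acquisition *geometry* this method
targets — six channels at 250 Hz, 10-s sessions — with per-channel stable
AR dynamics, independent Gaussian excitation per channel, and an optional
additive 60 Hz line component common to all channels. Classes differ by
their per-channel reflection signatures, so ground truth in feature space
is known exactly, and every pipeline stage (notch, normalization, framing,
feature recovery, classification) is testable end-to-end.

It deliberately does **not** emulate physiological EEG: no $1/f$
background, no within-session nonstationarity, no ocular or muscle
artifacts, no cross-channel correlation (available only as an extension
point), and no subject variability. Passing tests on this generator
demonstrate that the algorithms are implemented correctly and recover
known structure; they do not demonstrate classification accuracy on real
recordings, which depends on unknowable real task signatures and on SVM
hyperparameters that published work leaves unreported.

## Problem sizes

The test-suite and acceptance computations use: 1000 random stable models
for the recursion-vs-direct-solve equivalence and the order-extension
property; $10^5$-sample realizations for parameter recovery (observed
error well inside ±0.02); and 10 sessions per class (380 frames) for the
end-to-end leave-one-out runs — enough frames that the chance-level run's
session-to-session variation stays well inside the 35–65 % band while the
separable pair reaches essentially perfect accuracy.

## Known limitations

* EDF support covers continuous 16-bit recordings with one common sampling
  rate; annotation channels and per-signal rates are rejected.
* Frame-level leave-one-out optimism, as discussed above.
* The quadratic/polynomial kernel offset and the penalty $C$ are package
  defaults, not values tied to any published experiment; comparisons
  against published accuracy tables are out of scope.
* Band-limited feature extraction (`bandpass` + reflection features) uses
  one fixed 4th-order Butterworth design per band; very narrow low bands
  (delta) at 250 Hz are near the edge of what a low-order IIR magnitude
  response represents well.
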