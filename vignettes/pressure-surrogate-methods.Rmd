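---
title: "Estimating subglottal pressure with a simulation-trained recurrent surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subglottal pressure with a simulation-trained recurrent surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The subglottal pressure `Ps` — the air pressure below the vocal folds that
drives their self-sustained oscillation — is a central parameter in voice
physiology, but it cannot be measured directly in vivo. A classical indirect
route is an inverse problem: record the medio-lateral motion of the vocal
fold edges with high-speed video, then search for the configuration of a
lumped-element vocal-fold model whose simulated motion best matches the
recording. That optimization must be repeated from scratch for every new
recording and requires tens of thousands of forward-model evaluations each
time.

`subglot` implements the surrogate alternative: simulate a large labeled
corpus of trajectories across a wide space of model configurations **once**,
make the synthetic trajectories look like experimental ones, and train a
recurrent classifier that maps a short trajectory window directly to a
pressure estimate. After the one-time training, a new recording costs a
single network evaluation instead of a fresh optimization.

## The two-mass model

Each vocal fold is reduced to two point masses (a lower and an upper plate)
that move laterally. With `s ∈ {l, r}` indexing the side and `i ∈ {1, 2}`
the plane, each mass obeys

    m_{s,i} ẍ_{s,i} = F^a_{s,i} + F^v_{s,i} + F^c_{s,i} + F^d_{s,i}

with

* **anchor force** `F^a = −k_{s,i} x_{s,i} − r_{s,i} ẋ_{s,i}`: a linear
  spring to the resting position plus viscous damping, representing the
  stiffness of the fold tissue;
* **vertical coupling** `F^v = −kc (x_{s,i} − x_{s,j})`: a spring between
  the two masses of one side, representing shear within the fold;
* **collision force** `F^c = −Θ(−a_i) c_{s,i} a_i/(2L)`: an extra
  restoring spring that engages only while the glottal area
  `a_i = a_{0i} + L (x_{l,i} + x_{r,i})` of plane `i` is negative, i.e.
  while the folds are in contact (`Θ` is the Heaviside step; an area of
  exactly zero counts as open, which is immaterial because the force
  vanishes there anyway);
* **driving force** `F^d = Ps L d₁ [1 − Θ(a_min)(a_min/a₁)²] Θ(a₁)` on the
  lower masses only: a Bernoulli flow model in which the pressure drops to
  zero at the narrowest open section `a_min = min(a₁, a₂)`; a closed lower
  plane shields the folds from the subglottal pressure, a closed upper
  plane above an open lower plane exposes them to all of it.

The model is integrated in the (g, cm, ms) unit system, in which a pressure
of 0.008 corresponds to 800 Pa. The symmetric reference constants
(`model_parameters()`) are the classic simplified set: m₁ = 0.125 g,
m₂ = 0.025 g, k₁ = 0.08, k₂ = 0.008, kc = 0.025 g/ms², r₁ = r₂ = 0.02 g/ms,
a₀₁ = a₀₂ = 0.05 cm², d₁ = 0.25 cm, L = 1.4 cm, and collision stiffness
`3 k_i`.

A simulated larynx is configured by six dimensionless factors
(`scaling_vector()`): per-side mass factors `Qm_l, Qm_r`, per-side stiffness
factors `Qk_l, Qk_r`, a pressure factor `QPs`, and a collision-strength
offset `Qkc` with effective collision stiffness `(1 + Qkc)·3·k_{s,i}` — so
`Qkc = −1` maps exactly to collision-free dynamics, which is why its lower
bound is −1. Asymmetric mass or stiffness factors produce the left/right
asymmetric vibration patterns typical of real (especially pathological)
larynges.

### Numerical choices

The equations are integrated with classical fixed-step 4th-order
Runge–Kutta. A fixed step keeps the output sampling grid exact and the
simulation bit-reproducible; adaptive steppers gain little here because the
collision force makes the right-hand side only piecewise smooth, and they
would make determinism across configurations harder to reason about. The
default step is `dt = 0.0125` ms (`oversample = 20` substeps per output
sample at 4000 Hz). This step was chosen so that halving it moves the
recorded default trajectory by less than 10⁻⁴ cm RMS; at twice the step
(oversample 10) the accumulated phase drift from collision events is orders
of magnitude larger. Convergence below ~2·10⁻⁵ cm RMS is not attainable by
step refinement alone — the collision non-smoothness limits the effective
order — but that floor is three orders of magnitude below typical
oscillation amplitudes (~5·10⁻² cm).

Each simulation starts from a slightly displaced rest state (0.01 cm on all
masses) and discards a 500 ms onset transient before recording 400 samples
(100 ms) at 4000 Hz, matching the length and rate of the experimental
recordings the pipeline emulates. Configurations that diverge numerically
(non-finite state or |x| > 100 cm) are flagged, not raised: batch generation
treats them like any other rejected configuration.

### What counts as phonation

Training labels only make sense for configurations that actually phonate.
`is_oscillatory()` requires, per channel: a displacement SD above 10⁻³ cm
(an order of magnitude below typical amplitudes, an order above the residue
of a decayed configuration); a dominant periodogram peak between 30 and
500 Hz (generously bracketing the 70–281 Hz fundamentals observed in the
ex vivo recordings); and at least 10% of non-DC periodogram power in that
peak ±2 bins. A 400-sample white-noise trajectory concentrates only a few
percent of its power in its largest bin, so the last criterion separates
noise-like from periodic motion with a wide margin on both sides.

## Synthetic data as a stand-in for experiments

The generator emulates the published characteristics of the 288 ex vivo
porcine recordings the method was originally evaluated against (those
recordings are not publicly deposited): paired quasi-periodic trajectories,
400 samples at 4000 Hz, fundamentals roughly 70–281 Hz, and pressure labels
whose mean matches the reported experimental mean of 996 Pa.

* **Configuration sampling.** Mass, stiffness and collision factors are
  uniform on [0.3, 4.0]⁴ × [−1.0, 8.0] — a deliberately wide, uninformative
  prior. The pressure factor is sampled in *pressure space* from
  N(996, 300²) Pa, truncated by rejection to the factor bounds
  [0.5, 2.5] (= 400–2000 Pa), so that the label distribution matches the
  experimental one and the balanced classes are roughly equally populated.
  The experimental standard deviation was never published numerically;
  300 Pa is this package's documented choice, wide enough to cover the
  392–1960 Pa class range without concentrating labels at the truncation
  edges.
* **Label calibration.** The two-mass model systematically underestimates
  the driving pressure relative to experiment; a multiplicative
  `calibration_factor` on the labels compensates. The package default is
  1.0 (no correction): the factor found in the original optimization study
  is not published, and any constant factor is transparent to the
  *synthetic* validation metrics this package can verify (it rescales
  labels and class bounds together). For transfer to real recordings a
  factor around 1.6 (the ratio of uncalibrated to calibrated baseline MAE,
  284/173) is a documented starting point.
* **Noise.** Additive i.i.d. Gaussian noise with SD `0.075 σ`, where σ is
  the SD of the channel the noise is added to, emulating camera and
  segmentation noise. Noise is drawn independently per channel; the two
  edges are segmented independently in practice.
* **Amplitude modulation.** Real folds show slow cycle-to-cycle amplitude
  variation. Six anchor values drawn from N(1, 5σ) at equally spaced times
  (endpoints included) are joined by a quadratic spline (piecewise
  quadratic, continuous first derivative, exact pass-through — a single
  global quadratic cannot interpolate six generic points), clipped at zero
  because a negative amplitude gain is meaningless, and multiplied into the
  signal. The `5σ` width is taken literally from its source and is
  configurable (`env_sd_scale`); with typical σ ≈ 0.03 cm it yields mild
  ±15% modulation.
* **Cropping.** The estimator sees 50-sample windows (12.5 ms): at 70–281 Hz
  a window covers one to several full cycles, and all present frequencies
  are far below the 2000 Hz Nyquist limit, so little information is lost
  while the network input stays small. Augmentation is applied to the full
  400-sample trajectory *before* cropping, so its statistics do not depend
  on the crop offset. Training uses one crop per trajectory (fresh
  simulated trajectories are cheap); the 16-crops-per-recording protocol is
  reserved for emulating the experimental test procedure
  (`predict_recording()`), where 288 recordings × 16 windows = 4608 test
  samples.
* **Window preprocessing.** Each window is mean-centered jointly over both
  channels, which removes the (physically meaningless) absolute resting
  position but **keeps the displacement scale**: oscillation amplitude
  grows with driving pressure and is the estimator's single strongest cue.
  Full joint mean/SD normalization (`normalize_window()`) is available as
  `normalize = "full"` for inputs whose length calibration is unknown, but
  it demonstrably removes most of the label information — with it, even a
  flexible nonparametric regressor on rich shape features barely improves
  on always predicting the mean label. Using physical displacement presumes
  calibrated trajectories (ex vivo recordings in this lineage are
  laser-calibrated); uncalibrated pixel trajectories would need a length
  calibration first.
* **Splitting.** 8:2 train/validation split over *trajectories*, not
  windows, so no simulated trajectory leaks across the split.

Every attempted configuration runs under its own sub-seed derived from the
dataset seed and the attempt index, recorded in the provenance table; a
stored sample can be re-simulated bit-exactly (`resimulate_sample()`), and
two runs with the same seed produce byte-identical datasets.

What the generator does **not** emulate: segmentation artifacts beyond
additive noise, posterior-gap geometry, vertical (superior–inferior) fold
motion, frequency jitter within a trajectory, and acoustic source–filter
coupling. Passing the synthetic validation therefore shows that the
estimator inverts the model family it was trained on under realistic noise
— it does not by itself establish accuracy on real video data.

## From regression to balanced classification

Rather than regressing the scalar pressure directly, the target is
discretized into `K` classes `C_i = {y | L_i ≤ y < U_i}` between
`L₀ = 392` Pa and `U_K = 1960` Pa. Because the labels are approximately
Gaussian, equally *wide* classes would be very unequally *populated*;
instead the bounds are Gaussian quantiles — computed from the CDF of a
normal with the training labels' sample mean and SD — so every class
carries equal probability mass (`build_binning()`; equality holds to 10⁻⁹
relative). A predicted class decodes to its interval midpoint
`(L_i + U_i)/2`. Labels pushed slightly out of range (e.g. by calibration)
clamp to the edge classes. The default granularity is `K = 1007` classes;
at that granularity the quantization error contributed by midpoint decoding
is small against the network's own error.

## The estimator

A single LSTM layer (128 cells) reads the 50×2 window; its last-step output
passes through dropout (p = 0.5, training only) into a dense softmax layer
with `K` outputs. Training minimizes cross-entropy with Adam (learning rate
0.001, batch 100) and global-norm gradient clipping at 5.0. Early stopping
monitors the validation loss with patience 5, armed only after a 20-epoch
warm-up ("after initial convergence"); the hard cap is 400 epochs. The
weights at the stopping epoch are kept — no best-epoch rollback, matching
the stopping rule taken literally. Ten independently initialized runs are
trained and metrics averaged across runs, because run-to-run variability
from random initialization is non-negligible.

There is no deep-learning framework behind this: the LSTM forward pass,
backpropagation through time, Adam, clipping and dropout are implemented in
the package's own compiled code (RcppArmadillo), with *all* randomness —
initialization (Glorot-uniform weights, forget-gate bias 1), batch
shuffling, dropout masks — drawn from R's RNG. A fixed `set.seed()`
therefore reproduces a training trajectory exactly, which the test suite
exploits.

Design points that were genuinely open and decided here: the classifier
reads the last time step's hidden state (standard many-to-one topology)
rather than pooling over steps; clipping is by global norm with threshold 5
(only "gradient clipping" is specified by the source); the warm-up is 20
epochs; validation windows get a single crop.

## Error metrics

`score()` reports MAPE (`100·mean|ŷ−y|/y`), MAE, signed-error mean and SD,
absolute-error quartiles (linear interpolation between order statistics),
and the fraction of absolute errors below 35 Pa — the reproduction accuracy
of the pressure transducer used in the ex vivo experiments, i.e. the point
past which a better estimator could not be distinguished from the sensor
itself. Metrics are computed per run and then averaged; SDs are across
runs. The mean-predictor baseline (`baseline_report()`) — predict the
training-label mean for every window — is the floor any useful estimator
must clearly beat. `efficiency_ratio()` quantifies the point of the whole
exercise: a per-recording optimization lineage needed ~4.32·10⁷ forward
simulations for 288 recordings, against 4·10⁴ simulations for one-time
training — 1080× fewer.

## Problem sizes used in the shipped checks

The package's automated checks run a reduced version of the full study,
chosen to exercise every stage at meaningful scale on a single CPU: 8000
windows (6400 train / 1600 validation), `K = 101` classes, one training run
capped at 40 epochs. At that scale the checks compare the trained estimator
against the mean-predictor baseline (the strictest check asks for a twofold
MAPE reduction, which sits right at the edge of what this scale supports
under the literal early-stopping rule — the validation loss plateaus while
the decoded error is still falling) and require the median absolute error
to stay within the widest class width. The full-scale configuration of the original
study (40 000 windows, `K = 1007`, 10 runs, up to 400 epochs) is the
package default (`pipeline_config()`) and runs unattended in hours on a
single CPU; `scripts/acceptance.R` re-runs the reduced study end-to-end and
writes every computed metric to JSON.

## Known limitations

* The exact force expressions of the original study's "slightly modified"
  two-mass model are not published; this package implements the canonical
  simplified form its lineage builds on. Absolute simulated amplitudes and
  thresholds can differ from that study's in detail.
* The observable is the *lower*-mass displacement (the medially visible
  edge in high-speed video); whether the original study tracked the lower
  mass, upper mass, or minimum-area edge is not stated.
* The experimental recordings are not deposited, so sim-to-real transfer
  error (the original test MAPE on porcine data) cannot be reproduced here;
  only the synthetic-validation side is verifiable.
* Labels below 392 Pa or above 1960 Pa are not representable by decoding;
  the estimator is a within-range instrument.
* With `normalize = "full"` the pipeline is calibration-free but loses most
  of its accuracy; with the default `"center"` it requires physically
  calibrated displacements.
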