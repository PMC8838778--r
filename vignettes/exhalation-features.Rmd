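---
title: "Exhalation acoustics, Choi–Williams features and age-group recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhalation acoustics, Choi–Williams features and age-group recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exhalr)
```

# The model

A forced exhalation is recorded at close range, the subject having taken a
deep breath and blown as hard and as long as possible. Because the vocal
cords are inactive during a blow, the signal is modelled as broadband noise
shaped by the vocal tract: hot blows occupy roughly 450–1300 Hz and cold
blows — the kind a spirometry manoeuvre produces — 1500–4000 Hz. The
analysis makes no attempt to recover calibrated flow in litres; instead it
summarises each recording with 42 features whose joint distribution is
expected to shift with lung function, and therefore with lung age.

## Spirometer-like features

The recording is peak-normalised once at load (microphone gain at ~20 cm
is uncontrolled) and decomposed with a Hann-windowed STFT (`n_fft = 2048`,
`hop = 512` samples at the canonical 44,100 Hz — the de facto audio
analysis defaults, both configurable). Magnitudes become decibels relative
to the spectrogram maximum and are floored at −80 dB. Three scalars mimic
the classic spirometric measures:

* `total_dec` — the sum of |dB| over every bin and frame. A louder, longer
  effective exhalation keeps bins above the floor for longer, so the sum
  tracks total expelled volume (FVC).
* `total_dec_1st_sec` — the same sum over frames whose *centre* time lies
  in the half-open interval [0, 1) s (FEV1). Centre time, not start time,
  so a frame is counted where most of its energy lies.
* `max_peak` — with max-referenced decibels the literal "loudest decibel"
  is 0 by construction, so the peak is reported as the dynamic range
  `max(dB) − min(dB)` (PEF intent: peak flow above the floor). Note the
  consequence: any recording whose spectrogram spans the full floored
  range returns exactly the floor value (80 dB with the defaults). On
  synthetic band-noise corpora this feature is therefore constant; the
  prescreening chain tolerates and discards constant columns.

The dB reference choice makes all three features invariant to recording
level. The reference (the spectrogram maximum) is itself a random quantity
of the noise process, which injects common-mode variance into `total_dec`
and `total_dec_1st_sec`; classifiers that model feature covariance can
partially cancel it.

## Time-frequency features

Each recording is analysed in frames of 1024 samples every 512 samples.
For a frame x(t), the analytic signal x_a is built by the FFT–Hilbert
construction, and its discrete Wigner–Ville distribution is computed from
the instantaneous autocorrelation K(t, τ) = x_a(t+τ)·x_a*(t−τ) with lags
truncated at the frame edges. The FFT over τ yields 1024 frequency bins
spanning [0, f_s/2), i.e. a bin width of f_s/2048. The Wigner distribution
is smoothed in the ambiguity domain by the Choi–Williams kernel

  Φ(θ, τ) = exp(−(2πθτ)²/σ),

with θ in cycles/sample and τ in samples (σ = 1 by default). With this
convention the kernel is identically 1 on the θ = 0 axis, so
constant-frequency auto-terms pass untouched, while cross-terms — which
live at θ equal to the component separation — are strongly attenuated. As
σ → ∞ the kernel tends to 1 everywhere and the raw Wigner distribution is
recovered; the test suite asserts both properties. The smoothed matrix is
normalised to unit sum (CWDN); it may retain small negative values, as
bilinear distributions do.

The marginal densities are **not** obtained by summing CWDN. The time
marginal m_t(t) is the normalised instantaneous power |x_a(t)|², the
frequency marginal m_f(f) the normalised periodogram of x_a on the same
[0, f_s/2) grid. These are the Wigner distribution's theoretical marginals
and are non-negative by construction, so every logarithm below is defined
without sign gymnastics. The separable joint density is
p_D(f, t) = m_f(f)·m_t(t).

Over seven fixed bands (0–80, 80–250, 250–550, 550–900, 900–1500,
1500–3000, 3000–Nyquist Hz; contiguous half-open intervals) four families
of per-band features are computed from p_D:

* `e_bn` — the time mean of the in-band energy E(t) = Σ_{f∈band} p_D(f,t).
  The band means over a partition of the axis sum to 1/n_t exactly.
* `f_cres` — the mean in-band arg-max frequency of p_D(f, t), the
  instantaneous frequency peak. Ties break toward the lowest bin. As
  printed, the defining formula carries a 1/E(t) scale on an arg-max; that
  factor is dropped because an arg-max is invariant to positive scaling
  and the result must stay in Hz within the band.
* `f_med` — the mean in-band energy-weighted frequency
  (1/E(t))·Σ f·p_D(f, t).
* `ie_bn` — the band mean of the spectral information −log₂ m_f(f), with
  densities floored at eps = 2⁻³⁰ inside the logarithm (so an empty bin
  contributes 30 bits).

Time samples with in-band energy at or below eps are excluded from the
per-band means; a band with no such samples reports 0 and is flagged
silent. Four global features follow: the entropies H_t, H_f and their sum
H_tf (with 1024 time samples and 1024 frequency bins the bound is
log₂ 1024 + log₂ 1024 = 20 bits, matching the stated 0–20-bit range); and
the kurtosis of m_t in the Pearson convention (Gaussian → 3, uniform →
9/5), read as the 4th standardised moment of the time marginal — the
frequency marginal enters with exponent zero. Finally six joint moments
tⁿfᵐ with n = m ∈ {1, 7, 15} are computed with both axes normalised to
(0, 1] (index over count, so order-15 powers cannot overflow): `momC` sums
over the signed CWDN matrix and `momM` multiplies the two marginal
moments. On a separable matrix the two coincide; computing `momC` on CWDN
rather than on p_D is deliberate, since under the separable density the
six would be pairwise identical and three features redundant.

Per-frame features are averaged across at most `max_frames = 8` frames
taken evenly spaced over the recording (near-silent frames skipped). A
six-second recording at 44.1 kHz offers ~515 overlapping frame positions;
for quasi-stationary band noise their features are exchangeable, so a
systematic subsample estimates the across-frame mean at a fraction of the
O(N²) cost of the full hop grid. The identity H_tf = H_t + H_f is linear
and survives averaging exactly.

# The synthetic generator

`synth_blow` draws seeded Gaussian noise, applies a 4th-order Butterworth
band-pass (forward–backward, hence zero-phase) at the blow type's band,
multiplies by a flow-rate envelope, adds optional broadband noise and
peak-normalises. The envelopes mirror the three canonical spirometry flow
shapes: *healthy* rises linearly to its peak at `t_peak = 0.2` s and
decays as exp(−λ(t−t_peak)) with λ = 0.5 s⁻¹; *obstructive* decays as
exp(−λ(t−t_peak)^1.6), faster than exponential, as increasing airway
obstruction produces; *restrictive* is a Weibull density (shape 2, scale
2.5 s) rescaled so its time integral is `capacity = 0.6` of the healthy
integral — reduced vital capacity with preserved shape. Default duration
is 6 s, consistent with a forced manoeuvre.

`synth_corpus` draws ages uniformly on [17, 67], balances genders, assigns
envelope classes at the configured proportions (default 70 % healthy,
15 % obstructive, 15 % restrictive — a volunteer population with a
minority of impaired patterns) and adds a broadband noise floor of 0.005
(≈ −46 dB re peak, quiet-room recording). Ageing acts monotonically: the
decay rate is scaled by (1 + 0.01·(age−17)) and the peak amplitude by
(1 − 0.005·(age−17)), so older subjects blow shorter and weaker. These
slopes are a stand-in for testing recovery, not a physiological claim; no
quantitative age–acoustics law is available to calibrate them.
`synth_features` streams generation and extraction so a 300-recording run
keeps constant memory (a materialised corpus of that size holds ~0.6 GB
of waveforms).

What the generator deliberately omits: room acoustics, environmental
noise events (speech, coughs), microphone frequency response, within-
subject repeat variability, and any true physiological coupling between
age and spectrum. Passing tests on this corpus therefore demonstrate that
the pipeline recovers a *planted* monotone acoustic ageing signal — not
that real exhalations carry one of this strength.

# Prescreening and evaluation

The prescreening chain is age-blind: a Pearson correlation filter drops,
for every pair with |r| > 0.9, the later feature in canonical column
order (`gender` is never dropped; constant columns are treated as
uncorrelated with a warning). PCA-based selection then standardises the
features, keeps the leading components reaching 99.9 % cumulative
explained variance, scores each original feature by Σ_c EVR_c·loading²,
and keeps the smallest prefix of features (by descending score) reaching
99.9 % of the total score. The end point is a named subset of original
features — preserving interpretability — rather than component scores;
this is one defensible realisation of a reduction reported as a list of
named features, and it is config-replaceable.

SMOTE balances class counts by interpolating each minority sample toward
one of its k = 5 nearest same-class neighbours with a uniform random
weight. Its placement matters: applied to the whole corpus before
splitting (`paper_mode = TRUE`, corpus-level balancing), synthetic points
derived from what later become test rows leak into training and inflate
accuracy — the test suite
demonstrates the inflation on label-permuted data. The default applies
SMOTE inside each training fold only.

Evaluation uses stratified 10-fold cross-validation (folds reduced to the
smallest class count when needed), per-fold standardisation by training
statistics, and eight classifiers at canonical defaults: k-NN (k = 5),
C-SVC (RBF, C = 1), random forest (300 trees), decision tree, Gaussian
naive Bayes, multinomial logistic regression (small L2 decay for
stability), LDA, and QDA. QDA is implemented in-package with shrinkage
regularisation, Σ_k ← (1−r)Σ_k + r·tr(Σ_k)/p·I with r = 0.1, because the
textbook estimator is singular whenever a class has fewer samples than
features — the usual situation with 11 age groups, ~30 surviving features
and a small corpus; the in-package estimator agrees with the reference
implementation on well-conditioned data (asserted in the tests).
Multiclass sensitivity and specificity are one-vs-rest macro averages
over classes present in the truth; for two classes the literal binary
definitions apply with the first class as positive. Classifiers are
compared by two-sided paired t-tests on fold-wise accuracies with
Bonferroni correction (α/28 for the full set of eight); zero-variance
differences are handled exactly (identical folds → p = 1, constant
non-zero difference → p = 0).

Ages are binned by `floor((age − 17)/width)` with widths 1–10 years; the
anchor at the minimum age and half-open bins are a convention choice.

# The recovery experiment

The acceptance-level recovery check asks the full pipeline (correlation
filter → PCA selection → fold-internal SMOTE → QDA, width 5) to beat
three times chance on a 300-sample corpus, and to fall back to chance
(± 10 points) under label permutation. This experiment uses a *controlled*
corpus: envelope class held at healthy and a strong age effect
(`lambda_slope = 0.04`, `energy_slope = 0.01` — decay rate tripling and
amplitude halving across the 50-year range). Two design notes:

* At the generator's default slopes the planted signal's information
  ceiling (linear R² ≈ 0.73, residual ≈ 7 years) sits at the 3×-chance
  bar itself — no classifier can reliably clear a bar that equals the
  Bayes level. Recovery experiments are run with a strong effect so that
  failure indicts the pipeline, not the corpus.
* Holding the envelope class fixed is the standard way to isolate one
  generative parameter. With the mixed-envelope default, class-conditional
  feature distributions are three-modal and the Gaussian class model
  behind QDA is mis-specified: ensemble methods still clear 3× chance
  but QDA itself does not. That mismatch is a known limitation of
  QDA on heterogeneous populations, not of the feature set.

Problem sizes used by the shipped checks: 20 recordings for the
cardinality check, 50 for the entropy bound, 50 + 50 for spectral
placement, 300 for recovery — sizes at which each property is already
stable while a full run of the suite stays comfortably interactive.

# Numerical choices and degenerate inputs

* eps = 2⁻³⁰ floors densities inside logarithms and defines silence
  exclusion; at that floor an empty bin contributes −log₂ eps = 30 bits.
* Arg-max ties break toward the lowest frequency bin, deterministically.
* All-zero signals are rejected where a reference level or distribution
  would be undefined (`stft_db`, `choi_williams`); silent recordings are
  excluded (with reasons) during assembly rather than propagated.
* Resampling is Fourier-domain truncation/zero-padding — exact for
  band-limited content; energy drift on band-limited input is below 1 %.
* Every stochastic stage (corpus, SMOTE, folds, stochastic classifiers)
  is driven by explicit seeds; generation is a pure function of
  (parameters, seed) and restores the caller's RNG state.
* The Choi–Williams matrices are computed in compiled code (FFTW-backed);
  a 1024-sample frame costs ~60 ms, so a six-second recording is
  summarised in well under a second.

# Known limitations

* `max_peak` is constant on recordings whose spectrograms span the full
  floored dynamic range (see above); it carries information only for
  recordings quieter than the floor.
* The 3000-Nyquist band tops out at 22,050 Hz at the canonical rate; band
  edges are fixed in Hz, so resampling to other rates changes only the
  last band's width.
* Per-frame analysis bounds the entropy features by the frame length;
  features describing the slow flow envelope (decay shape) are carried by
  the spectrogram sums, not by the per-frame marginals.
* QDA on mixed populations (multiple envelope classes per age group) is
  mis-specified; prefer RF or LDA there, or stratify by envelope.
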