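# exhalr

Estimate a person's *lung age* — the age group whose typical lung function
matches theirs — from nothing but the sound of a forced exhalation recorded
by an ordinary microphone. The package is aimed at digital-spirometry
researchers who want a reproducible, end-to-end pipeline: audio in,
acoustic features out, age-group classification with honest
cross-validation at the end.

During a blow the vocal cords are inactive, so an exhalation is well
approximated by white noise shaped by a band-pass filter: *hot* blows (as
when fogging a window) concentrate energy near 450–1300 Hz, *cold* blows
(as when cooling soup, and the type a spirometry manoeuvre produces) near
1500–4000 Hz. `exhalr` quantifies each recording with 42 features:

* **gender** (0/1);
* **spirometer-like features** from a Hann-windowed STFT spectrogram in
  max-referenced decibels: `total_dec` = Σ|dB| over all bins (an FVC
  analogue), `total_dec_1st_sec` = the same sum over frames with centre
  time < 1 s (FEV1 analogue), and `max_peak` = the dynamic range
  max(dB) − min(dB) (PEF analogue);
* **38 time-frequency features** from the normalised Choi–Williams
  distribution CWDN(f, t) — the Wigner–Ville distribution of the analytic
  signal smoothed in the ambiguity domain by exp(−(2πθτ)²/σ) — and the
  separable density p_D(f, t) = m_t(t)·m_f(f) built from its marginals:
  per-band mean instantaneous energy E(t), instantaneous frequency peak
  f_Cres(t), mean instantaneous frequency f_mi(t) and spectral information
  −log₂ m_f(f) over seven fixed bands (0–80, 80–250, 250–550, 550–900,
  900–1500, 1500–3000, 3000–Nyquist Hz), plus the entropies
  H_t = −Σ m_t log₂ m_t, H_f = −Σ m_f log₂ m_f, H_tf = H_t + H_f
  (0–20 bits at the default discretisation), the kurtosis of m_t, and six
  joint moments tⁿfᵐ (n = m ∈ {1, 7, 15}) of CWDN (`momC..`) and of the
  marginal product (`momM..`).

Feature tables are prescreened the way the field does it — Pearson
correlation filter (|r| > 0.9 drops the later column), PCA-based selection
keeping the features that explain 99.9 % of the variance, SMOTE
oversampling to balance age groups — and fed to eight classifiers (k-NN,
C-SVC, RF with 300 trees, decision tree, naive Bayes, logistic regression,
LDA, QDA) under stratified k-fold cross-validation, with
Bonferroni-corrected paired t-tests between classifiers. By default SMOTE
runs *inside* each training fold; `paper_mode = TRUE` balances the whole
corpus before splitting, which leaks neighbourhood information and
visibly inflates metrics — both modes are first-class so the difference
can be studied.

A seeded synthetic blow generator (`synth_blow`, `synth_corpus`) emulates
the acoustics above with flow-rate envelopes shaped like the three
canonical spirometry curves (healthy: exponential decay; obstructive:
faster-than-exponential; restrictive: Weibull-shaped with reduced
capacity), so the entire pipeline is testable without a clinical corpus.

## Worked example

```r
library(exhalr)

sig <- synth_blow(blow_params("cold", "healthy", seed = 42))
print(sig)
#> <audio_signal: 264600 samples @ 44100 Hz (6.000 s), peak 0.9000>
validate_exhalation(sig)
#> <validation: ok; 6.00 s, clipped 0.000>

round(spiro_features(normalize_peak(sig)), 1)
#>         total_dec total_dec_1st_sec          max_peak
#>          36795586           5876943                80

tf <- extract_tf_features(sig)
round(tf[c("e_bn3", "e_bn6", "h_t", "h_f", "h_tf", "k")], 4)
#>   e_bn3   e_bn6     h_t     h_f    h_tf       k
#>  0.0000  0.0006  9.3427  6.4184 15.7611  2.0243
```

The cold blow puts its band energy in band 6 (1500–3000 Hz), not band 3
(250–550 Hz); its joint entropy (15.76 bits) sits inside the 0–20-bit
range; `max_peak` saturates at the 80 dB spectrogram floor. A small
end-to-end run — synthesise a 40-recording corpus with a strong monotone
age effect, extract features, prescreen, classify 10-year age groups:

```r
tbl <- synth_features(corpus_spec(40, class_proportions = c(healthy = 1),
                                  lambda_slope = 0.04, energy_slope = 0.01,
                                  seed = 1))
ps <- prescreen(tbl)
ps$report
#> Prescreening report
#>   dropped by correlation: e_bn6, e_bn7, f_med7, ie_bn2, ... h_f, h_tf, ...
#>   kept after PCA selection: 24 features
labels <- bin_ages(tbl$age, age_binning(17, 67, 10))
train_eval(ps$table, labels, "qda", k = 5, seed = 1)
#> <eval: qda | acc 0.475 sens 0.373 spec 0.859 | 5 folds>
```

Five 10-year groups, chance accuracy 0.2; QDA reaches 0.475 on 40
samples. `run_experiment()` evaluates the full width × classifier grid
(widths 1, 2, 3, 4, 5, 10 years) and returns the metric table plus the
pairwise significance matrices.

## Command line

```sh
exec/exhalr synth    --config corpus.cfg --out data/
exec/exhalr extract  --config extract.cfg
exec/exhalr evaluate --config eval.cfg --widths 5 --classifiers qda,rf
```

Config files are flat `key = value` text (see `?read_run_config`); every
run writes a JSON snapshot sufficient to reproduce it bit-for-bit.

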