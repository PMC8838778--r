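# Independent oracles used across the suite. All are deliberately naive
# (explicit loops over the defining formulas) so they stay independent of
# the package's vectorised/compiled implementations.

# Brute-force discrete Wigner-Ville of a complex frame: double loop over
# time and wrapped lag, K(t, tau) = x(t+tau) * Conj(x(t-tau)) truncated at
# the frame edges, then an explicit DFT over the lag.
brute_wigner <- function(x) {
  n <- length(x)
  W <- matrix(0, n, n)
  for (t in 1:n) {
    for (k in 1:n) {
      s <- 0 + 0i
      for (j in 0:(n - 1)) {
        tau <- if (j < n / 2) j else j - n
        i1 <- t + tau; i2 <- t - tau
        if (i1 >= 1 && i1 <= n && i2 >= 1 && i2 <= n)
          s <- s + x[i1] * Conj(x[i2]) * exp(-2i * pi * (k - 1) * j / n)
      }
      W[k, t] <- Re(s)
    }
  }
  W
}

# Brute-force band features: loop the defining per-time formulas over an
# explicit joint-density matrix.
brute_band_energy <- function(pD, freqs, band) {
  E <- numeric(ncol(pD))
  for (t in seq_len(ncol(pD))) {
    for (i in seq_len(nrow(pD))) {
      if (freqs[i] >= band[1] && freqs[i] < band[2])
        E[t] <- E[t] + pD[i, t]
    }
  }
  list(E = E, mean = mean(E))
}

brute_band_freq_peak <- function(pD, freqs, band, eps = 2^-30) {
  vals <- c()
  for (t in seq_len(ncol(pD))) {
    inb <- which(freqs >= band[1] & freqs < band[2])
    if (length(inb) == 0) next
    E <- sum(pD[inb, t])
    if (E > eps) vals <- c(vals, freqs[inb][which.max(pD[inb, t])])
  }
  if (length(vals) == 0) 0 else mean(vals)
}

brute_band_freq_mean <- function(pD, freqs, band, eps = 2^-30) {
  vals <- c()
  for (t in seq_len(ncol(pD))) {
    inb <- which(freqs >= band[1] & freqs < band[2])
    if (length(inb) == 0) next
    E <- sum(pD[inb, t])
    if (E > eps) vals <- c(vals, sum(freqs[inb] * pD[inb, t]) / E)
  }
  if (length(vals) == 0) 0 else mean(vals)
}

brute_band_spectral_info <- function(mfN, freqs, band, eps = 2^-30) {
  inb <- which(freqs >= band[1] & freqs < band[2])
  if (length(inb) == 0) return(0)
  mean(sapply(inb, function(i) -log2(max(mfN[i], eps))))
}

# Trapezoid quadrature on a fine grid.
trapz <- function(f, lo, hi, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Dominant periodogram frequency of a real signal.
dft_peak_hz <- function(x, fs) {
  p <- Mod(fft(x))^2
  half <- seq_len(floor(length(x) / 2))
  (which.max(p[half]) - 1) * fs / length(x)
}

# Fraction of periodogram energy inside a band (positive frequencies).
band_energy_fraction <- function(x, fs, band) {
  p <- Mod(fft(x))^2
  n <- length(x)
  fr <- (seq_len(n) - 1) * fs / n
  half <- fr < fs / 2
  sum(p[half & fr >= band[1] & fr <= band[2]]) / sum(p[half])
}

# A pure tone as an audio_signal.
tone_signal <- function(freq, fs = 44100, dur = 1) {
  audio_signal(sin(2 * pi * freq * (0:(round(fs * dur) - 1)) / fs), fs)
}

# Evaluate with a local RNG seed without disturbing the suite's stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Drop bookkeeping attributes before comparing feature tables.
strip_attrs <- function(d) {
  attr(d, "excluded") <- NULL
  as.data.frame(d)
}

# Small deterministic feature-table stand-in (numeric columns only).
fake_feature_table <- function(X, age = NULL) {
  df <- as.data.frame(X)
  df <- cbind(sample_id = sprintf("s%03d", seq_len(nrow(df))), df)
  if (!is.null(age)) df$age <- age
  class(df) <- c("feature_table", "data.frame")
  df
}
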