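## The 38 time-frequency features: four per-band families over 7 fixed
## frequency bands (instantaneous spectral energy, instantaneous frequency
## peak, instantaneous mean frequency, spectral information), plus global
## entropies, kurtosis of the time marginal and six joint moments.

#' The seven analysis frequency bands
#'
#' Default edges 0-80, 80-250, 250-550, 550-900, 900-1500, 1500-3000 and
#' 3000-Nyquist Hz: contiguous half-open `[low, high)` intervals covering
#' `[0, Nyquist]`. The bands bracket where hot (450-1300 Hz) and cold
#' (1500-4000 Hz) blow energy sits.
#'
#' @param sample_rate Sampling rate in Hz (sets the Nyquist upper edge).
#' @param edges Optional 7 x 2 matrix of custom `(low, high)` pairs.
#' @return A `band_set`: 7 x 2 numeric matrix with columns `low`, `high`.
#' @export
band_set <- function(sample_rate = 44100, edges = NULL) {
  if (is.null(edges)) {
    lows <- c(0, 80, 250, 550, 900, 1500, 3000)
    highs <- c(80, 250, 550, 900, 1500, 3000, sample_rate / 2)
    edges <- cbind(low = lows, high = highs)
  } else {
    edges <- as.matrix(edges)
    colnames(edges) <- c("low", "high")
  }
  if (nrow(edges) != 7L) stop("a band set has exactly 7 bands")
  if (any(edges[, 2] <= edges[, 1])) stop("band edges must be increasing")
  if (any(abs(edges[-1, 1] - edges[-7, 2]) > 1e-9))
    stop("bands must be contiguous")
  structure(edges, class = "band_set")
}

band_bins <- function(freqs, band) {
  which(freqs >= band[1] & freqs < band[2])
}

#' Instantaneous spectral energy of a band
#'
#' `E(t) = sum over f in band of pD(f, t)`; the feature is its time mean.
#'
#' @param pD Joint density matrix (frequency x time).
#' @param freqs Frequency of each row, Hz.
#' @param band Numeric `c(low, high)` in Hz.
#' @return List with `E` (the per-time sequence) and `mean`.
#' @export
band_energy <- function(pD, freqs, band) {
  if (band[1] < 0 || band[1] > max(freqs))
    stop("band lies outside the frequency axis")
  bins <- band_bins(freqs, band)
  if (length(bins) == 0)
    return(list(E = numeric(ncol(pD)), mean = 0))
  E <- colSums(pD[bins, , drop = FALSE])
  list(E = E, mean = mean(E))
}

#' Mean instantaneous frequency peak of a band
#'
#' Per time sample with in-band energy above `eps`, the frequency of the
#' largest in-band density value (ties broken toward the lowest bin);
#' the feature is the mean over included times. Returns 0 with attribute
#' `silent = TRUE` when every time sample is excluded.
#'
#' @inheritParams band_energy
#' @param eps Energy floor below which a time sample is excluded.
#' @return Scalar frequency in Hz (attribute `silent` flags an empty band).
#' @export
band_freq_peak <- function(pD, freqs, band, eps = 2^-30) {
  bins <- band_bins(freqs, band)
  if (length(bins) == 0) return(structure(0, silent = TRUE))
  sub <- pD[bins, , drop = FALSE]
  E <- colSums(sub)
  keep <- E > eps
  if (!any(keep)) return(structure(0, silent = TRUE))
  idx <- max.col(t(sub[, keep, drop = FALSE]), ties.method = "first")
  structure(mean(freqs[bins][idx]), silent = FALSE)
}

#' Mean instantaneous frequency of a band
#'
#' Per time sample with in-band energy above `eps`, the density-weighted
#' mean in-band frequency `sum(f * pD(f, t)) / E(t)`; the feature is the
#' mean over included times.
#'
#' @inheritParams band_freq_peak
#' @return Scalar frequency in Hz (attribute `silent` flags an empty band).
#' @export
band_freq_mean <- function(pD, freqs, band, eps = 2^-30) {
  bins <- band_bins(freqs, band)
  if (length(bins) == 0) return(structure(0, silent = TRUE))
  sub <- pD[bins, , drop = FALSE]
  E <- colSums(sub)
  keep <- E > eps
  if (!any(keep)) return(structure(0, silent = TRUE))
  fmi <- colSums(sub[, keep, drop = FALSE] * freqs[bins]) / E[keep]
  structure(mean(fmi), silent = FALSE)
}

#' Mean spectral information of a band
#'
#' Mean over in-band frequency bins of `-log2(max(mfN(f), eps))` bits.
#'
#' @param mfN Unit-sum frequency marginal density.
#' @param freqs Frequency of each bin, Hz.
#' @param band Numeric `c(low, high)` in Hz.
#' @param eps Density floor inside the logarithm.
#' @return Scalar in bits (0 for a binless band).
#' @export
band_spectral_info <- function(mfN, freqs, band, eps = 2^-30) {
  bins <- band_bins(freqs, band)
  if (length(bins) == 0) return(0)
  mean(-log2(pmax(mfN[bins], eps)))
}

#' Shannon entropies of the marginal densities
#'
#' `h_t = -sum(mtN * log2(mtN))` (instantaneous entropy), `h_f` likewise
#' for the frequency marginal (spectral entropy), and their sum `h_tf`
#' (joint entropy of the separable density). Terms with zero mass
#' contribute zero.
#'
#' @param mtN,mfN Unit-sum non-negative densities.
#' @return Named vector `h_t`, `h_f`, `h_tf` in bits.
#' @export
entropies <- function(mtN, mfN) {
  if (abs(sum(mtN) - 1) > 1e-6 || abs(sum(mfN) - 1) > 1e-6)
    stop("marginal densities must sum to 1")
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_t <- ent(mtN); h_f <- ent(mfN)
  c(h_t = h_t, h_f = h_f, h_tf = h_t + h_f)
}

#' Kurtosis of the time marginal
#'
#' Pearson (non-excess) kurtosis `mu4 / mu2^2` of time viewed as a random
#' variable with density `mtN`, with time normalised to `[0, 1]`
#' (kurtosis is scale-invariant, so the normalisation only guards the
#' moment arithmetic). A Gaussian density gives 3, a uniform one 9/5.
#'
#' @param mtN Unit-sum density over time samples.
#' @param times Time of each sample (any affine scale).
#' @return Scalar kurtosis.
#' @export
tf_kurtosis <- function(mtN, times) {
  if (abs(sum(mtN) - 1) > 1e-6) stop("`mtN` must sum to 1")
  rng <- range(times)
  tn <- if (diff(rng) > 0) (times - rng[1]) / diff(rng) else times * 0
  mu <- sum(tn * mtN)
  mu2 <- sum((tn - mu)^2 * mtN)
  if (mu2 <= 0) stop("zero variance: kurtosis undefined")
  sum((tn - mu)^4 * mtN) / mu2^2
}

#' Joint time-frequency moments
#'
#' Moments `t^n f^m` for `n = m` in `{1, 7, 15}`, with both axes
#' normalised to `(0, 1]` (index over count). `momC` sums over the signed
#' smoothed Choi-Williams matrix; `momM` is the product of the two marginal
#' moments (they coincide exactly when the matrix is separable).
#'
#' @param cwdn Normalised (unit-sum) distribution matrix, frequency x time.
#' @param mtN,mfN Unit-sum marginal densities.
#' @return Named vector `momc11`, `momc77`, `momc15`, `momm11`, `momm77`,
#'   `momm15`.
#' @export
joint_moments <- function(cwdn, mtN, mfN) {
  nt <- length(mtN); nf <- length(mfN)
  tn <- seq_len(nt) / nt
  fn <- seq_len(nf) / nf
  momc <- vapply(c(1, 7, 15), function(k)
    as.numeric(crossprod(fn^k, cwdn %*% tn^k)), 0)
  momm <- vapply(c(1, 7, 15), function(k)
    sum(tn^k * mtN) * sum(fn^k * mfN), 0)
  c(momc11 = momc[1], momc77 = momc[2], momc15 = momc[3],
    momm11 = momm[1], momm77 = momm[2], momm15 = momm[3])
}

#' Names of the 38 time-frequency features
#' @return Character vector of length 38.
#' @export
tf_feature_names <- function() {
  c(paste0("e_bn", 1:7), paste0("f_cres", 1:7), paste0("f_med", 1:7),
    paste0("ie_bn", 1:7), "h_t", "h_f", "h_tf", "k",
    "momc11", "momc77", "momc15", "momm11", "momm77", "momm15")
}

## Per-frame features. Band features exploit the separability of
## pD = outer(mfN, mtN): E(t) = mass_band * mtN(t), the in-band arg-max and
## density-weighted mean frequency are time-invariant, so the across-time
## means collapse to closed forms identical to looping over the defining
## equations (the equivalence is asserted against brute-force loops in the
## test suite).
frame_tf_features <- function(tfd, bands, eps) {
  mtN <- tfd$mtN; mfN <- tfd$mfN; freqs <- tfd$freqs
  nb <- nrow(bands)
  e_bn <- f_cres <- f_med <- ie_bn <- numeric(nb)
  for (b in seq_len(nb)) {
    bins <- band_bins(freqs, bands[b, ])
    if (length(bins) == 0) next
    mass <- sum(mfN[bins])
    e_bn[b] <- mass * mean(mtN)
    included <- mass * mtN > eps
    if (any(included)) {
      f_cres[b] <- freqs[bins][which.max(mfN[bins])]
      f_med[b] <- sum(freqs[bins] * mfN[bins]) / mass
    }
    ie_bn[b] <- mean(-log2(pmax(mfN[bins], eps)))
  }
  ent <- entropies(mtN, mfN)
  k <- tf_kurtosis(mtN, tfd$times)
  mom <- joint_moments(tfd$cwdn, mtN, mfN)
  out <- c(e_bn, f_cres, f_med, ie_bn, ent, k = unname(k), mom)
  names(out) <- tf_feature_names()
  out
}

#' Extract the 38 time-frequency features of a recording
#'
#' Splits the signal into frames of `cfg$frame_len` samples every
#' `cfg$frame_hop` samples, keeps at most `cfg$max_frames` of them evenly
#' spaced across the recording (skipping near-silent frames), computes the
#' normalised Choi-Williams distribution and the per-frame features, and
#' returns the across-frame mean of each feature. Deterministic.
#'
#' @param sig An [audio_signal()].
#' @param cfg A [cwd_config()].
#' @param bands A [band_set()]; defaults to the standard edges with the
#'   upper band closing at the signal's Nyquist frequency.
#' @return Named numeric vector of the 38 features (see
#'   [tf_feature_names()]).
#' @export
extract_tf_features <- function(sig, cfg = cwd_config(), bands = NULL) {
  if (is.null(bands)) bands <- band_set(sample_rate = sig$sample_rate)
  n <- length(sig$samples)
  if (n < cfg$frame_len) stop("signal shorter than one analysis frame")
  starts <- seq(1L, n - cfg$frame_len + 1L, by = cfg$frame_hop)
  rms <- vapply(starts, function(s)
    sqrt(mean(sig$samples[s:(s + cfg$frame_len - 1L)]^2)), 0)
  starts <- starts[rms > 1e-8]
  if (length(starts) == 0) stop("no non-silent analysis frame found")
  if (length(starts) > cfg$max_frames)
    starts <- starts[unique(round(seq(1, length(starts),
                                      length.out = cfg$max_frames)))]
  kern <- cw_kernel(cfg$frame_len, cfg$sigma)
  acc <- matrix(0, length(starts), 38L)
  for (i in seq_along(starts)) {
    frame <- sig$samples[starts[i]:(starts[i] + cfg$frame_len - 1L)]
    tfd <- choi_williams(frame, cfg, sig$sample_rate, kernel = kern)
    acc[i, ] <- frame_tf_features(tfd, bands, cfg$eps)
  }
  out <- colMeans(acc)
  names(out) <- tf_feature_names()
  # the identity h_tf = h_t + h_f is linear, hence exact after averaging;
  # re-impose it to guard against floating-point drift
  out["h_tf"] <- out["h_t"] + out["h_f"]
  out
}
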