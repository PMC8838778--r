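## Wigner-Ville / Choi-Williams time-frequency analysis of a signal frame.
##
## The Wigner distribution of the analytic signal has high time-frequency
## resolution but oscillatory cross-terms between components; smoothing the
## ambiguity function with the Choi-Williams exponential kernel
## exp(-(2*pi*theta*tau)^2 / sigma) suppresses cross-terms (which live away
## from the ambiguity-plane axes) while preserving constant-frequency
## auto-terms exactly (the kernel is 1 on the theta = 0 axis).

#' Configuration for Choi-Williams feature extraction
#'
#' @param sigma Choi-Williams kernel parameter (> 0; larger means less
#'   smoothing, `Inf` recovers the raw Wigner distribution).
#' @param frame_len Analysis frame length in samples; a power of two
#'   at most 4096.
#' @param frame_hop Hop between frame starts in samples.
#' @param eps Density floor used inside logarithms and for silence
#'   exclusion (0 < eps <= 1e-6).
#' @param max_frames Upper bound on the number of analysis frames per
#'   recording; frames are taken evenly spaced across the signal and
#'   features are averaged over them.
#' @return A `cwd_config` list.
#' @export
cwd_config <- function(sigma = 1, frame_len = 1024L, frame_hop = 512L,
                       eps = 2^-30, max_frames = 8L) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (frame_len > 4096L || bitwAnd(frame_len, frame_len - 1L) != 0L)
    stop("`frame_len` must be a power of two at most 4096")
  if (frame_hop <= 0L) stop("`frame_hop` must be positive")
  if (eps <= 0 || eps > 1e-6) stop("`eps` must be in (0, 1e-6]")
  structure(list(sigma = sigma, frame_len = as.integer(frame_len),
                 frame_hop = as.integer(frame_hop), eps = eps,
                 max_frames = as.integer(max_frames)),
            class = "cwd_config")
}

#' Analytic signal of a real frame
#'
#' FFT-based Hilbert construction: negative frequencies are zeroed, positive
#' ones doubled; the real part of the result equals the input.
#'
#' @param frame Real numeric vector, length >= 16.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(frame) {
  n <- length(frame)
  if (n < 16L) stop("frame too short for analytic-signal construction")
  X <- fft(frame)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Raw Wigner-Ville distribution of a frame
#'
#' Discrete Wigner-Ville distribution of the analytic signal, without
#' Choi-Williams smoothing. Rows are frequency bins spanning `[0, fs/2)`
#' with spacing `fs / (2 * n)`, columns are time samples.
#'
#' @param frame Real numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @return Real matrix with attributes `freqs` and `times`.
#' @export
wigner_ville <- function(frame, sample_rate) {
  xa <- analytic_signal(frame)
  W <- cwd_frame_cpp(xa, 1, FALSE)
  n <- length(frame)
  attr(W, "freqs") <- (seq_len(n) - 1) * sample_rate / (2 * n)
  attr(W, "times") <- (seq_len(n) - 1) / sample_rate
  W
}

#' Normalised Choi-Williams distribution with marginal densities
#'
#' Computes the Wigner-Ville distribution of the frame's analytic signal,
#' smooths it with the Choi-Williams kernel in the ambiguity domain, and
#' normalises the result to unit sum. The time marginal `mtN` is the
#' normalised instantaneous power of the analytic signal and the frequency
#' marginal `mfN` its normalised periodogram on the same `[0, fs/2)` grid;
#' both are computed directly (not by summing the smoothed matrix) so they
#' are guaranteed non-negative and every logarithm downstream is defined.
#'
#' @param frame Real numeric vector of length `cfg$frame_len`.
#' @param cfg A [cwd_config()].
#' @param sample_rate Sampling rate in Hz.
#' @param kernel Optional precomputed kernel matrix from repeated calls at
#'   the same `(frame_len, sigma)` (see [cw_kernel()]).
#' @return A `tf_distribution`: `cwdn` (frequency x time, sums to 1; may
#'   hold small negative values), `mtN`, `mfN` (unit-sum non-negative
#'   densities), `times` (s), `freqs` (Hz).
#' @export
choi_williams <- function(frame, cfg = cwd_config(), sample_rate = 44100,
                          kernel = NULL) {
  n <- length(frame)
  if (n != cfg$frame_len)
    stop("frame length must equal cfg$frame_len (", cfg$frame_len, ")")
  if (all(frame == 0)) stop("all-zero frame: distribution undefined")
  xa <- analytic_signal(frame)
  W <- cwd_frame_cpp(xa, cfg$sigma, TRUE, kernel)
  cwdn <- W / sum(W)
  mt <- Mod(xa)^2
  mtN <- mt / sum(mt)
  Xa <- fft(c(xa, complex(n)))
  mf <- Mod(Xa[seq_len(n)])^2
  mfN <- mf / sum(mf)
  structure(list(cwdn = cwdn, mtN = mtN, mfN = mfN,
                 times = (seq_len(n) - 1) / sample_rate,
                 freqs = (seq_len(n) - 1) * sample_rate / (2 * n)),
            class = "tf_distribution")
}

#' Choi-Williams ambiguity-domain kernel matrix
#'
#' @param n Frame length.
#' @param sigma Kernel parameter.
#' @return `n x n` kernel matrix, FFT-wrapped layout.
#' @export
cw_kernel <- function(n, sigma) cw_kernel_cpp(as.integer(n), sigma)

#' Separable joint density of a time-frequency distribution
#'
#' Outer product of the frequency and time marginal densities,
#' `pD(f, t) = mfN(f) * mtN(t)`: non-negative and summing to 1.
#'
#' @param tfd A `tf_distribution` from [choi_williams()].
#' @return Matrix (frequency x time) with attributes `freqs` and `times`.
#' @export
joint_density <- function(tfd) {
  pD <- outer(tfd$mfN, tfd$mtN)
  attr(pD, "freqs") <- tfd$freqs
  attr(pD, "times") <- tfd$times
  pD
}
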