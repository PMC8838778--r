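## Spirometer-like features from an STFT decibel spectrogram.
##
## Total_dec (absolute dB sum over the whole spectrogram) approximates FVC,
## Total_dec_1st_sec (same, restricted to the first second) approximates
## FEV1, and Max_peak (the dynamic range between the loudest bin and the
## floor) approximates PEF. Decibels are referenced to the spectrogram
## maximum, so all three are invariant to recording gain.

#' Construct a spectrogram object
#'
#' Mostly used internally by [stft_db()]; exposed so that feature
#' arithmetic can be exercised on hand-built matrices.
#'
#' @param db Matrix of decibel values (frequency bin x time frame), max 0.
#' @param freqs Frequency of each bin, Hz.
#' @param times Centre time of each frame, seconds.
#' @param n_fft,hop STFT parameters in samples.
#' @param sample_rate Sampling rate in Hz.
#' @return A `spectrogram` object.
#' @export
spectrogram <- function(db, freqs, times, n_fft = NA_integer_,
                        hop = NA_integer_, sample_rate = NA_real_) {
  db <- as.matrix(db)
  if (length(db) == 0) stop("empty spectrogram matrix")
  structure(list(db = db, freqs = freqs, times = times, n_fft = n_fft,
                 hop = hop, sample_rate = sample_rate),
            class = "spectrogram")
}

#' Decibel spectrogram via the short-time Fourier transform
#'
#' Hann-windowed magnitude STFT converted to decibels relative to the
#' spectrogram maximum: `db = 20*log10(|S|/max|S|)`, floored at `-floor_db`.
#' The maximum of the result is therefore exactly 0 and the features built
#' on it do not depend on the recording level.
#'
#' @param sig An [audio_signal()].
#' @param n_fft FFT length in samples (>= 16).
#' @param hop Hop between frame starts in samples (0 < hop <= n_fft).
#' @param floor_db Dynamic-range floor in dB (values clipped at `-floor_db`).
#' @return A [spectrogram()] whose `times` are frame-centre times.
#' @export
stft_db <- function(sig, n_fft = 2048L, hop = 512L, floor_db = 80) {
  if (n_fft < 16L) stop("`n_fft` must be at least 16")
  if (hop <= 0L || hop > n_fft) stop("`hop` must satisfy 0 < hop <= n_fft")
  x <- sig$samples
  if (all(x == 0))
    stop("all-zero signal: dB reference level undefined")
  if (length(x) < n_fft)
    stop("signal shorter than one analysis frame")
  sp <- signal::specgram(x, n = n_fft, Fs = sig$sample_rate,
                         window = signal::hanning(n_fft),
                         overlap = n_fft - hop)
  mag <- Mod(sp$S)
  db <- 20 * log10(mag / max(mag))
  db <- pmax(db, -floor_db)
  n_frames <- ncol(db)
  times <- ((seq_len(n_frames) - 1) * hop + n_fft / 2) / sig$sample_rate
  spectrogram(db, freqs = as.numeric(sp$f), times = times, n_fft = n_fft,
              hop = hop, sample_rate = sig$sample_rate)
}

#' Total decibel sum (FVC-like)
#'
#' Sum of absolute decibel values over every frequency bin and time frame.
#'
#' @param spec A [spectrogram()].
#' @return Non-negative scalar.
#' @export
total_dec <- function(spec) {
  if (length(spec$db) == 0) stop("empty spectrogram")
  sum(abs(spec$db))
}

#' Decibel sum over the first second (FEV1-like)
#'
#' Sum of absolute decibels restricted to frames whose centre time lies in
#' the half-open interval `[0, 1)` second.
#'
#' @param spec A [spectrogram()].
#' @return Non-negative scalar (0 when no frame centre falls before 1 s).
#' @export
total_dec_1st_sec <- function(spec) {
  if (length(spec$db) == 0) stop("empty spectrogram")
  keep <- spec$times < 1.0
  if (!any(keep)) return(0)
  sum(abs(spec$db[, keep, drop = FALSE]))
}

#' Decibel dynamic range (PEF-like)
#'
#' With max-referenced decibels the literal "maximum decibel" is always 0,
#' so the peak is reported on the pre-normalisation scale as the dynamic
#' range between the loudest bin and the floor: `max(db) - min(db)`.
#'
#' @param spec A [spectrogram()].
#' @return Non-negative scalar in dB.
#' @export
max_peak <- function(spec) {
  if (length(spec$db) == 0) stop("empty spectrogram")
  max(spec$db) - min(spec$db)
}

#' The three spirometer-like features of a signal
#'
#' @inheritParams stft_db
#' @return Named numeric vector `total_dec`, `total_dec_1st_sec`, `max_peak`.
#' @export
spiro_features <- function(sig, n_fft = 2048L, hop = 512L, floor_db = 80) {
  spec <- stft_db(sig, n_fft = n_fft, hop = hop, floor_db = floor_db)
  c(total_dec = total_dec(spec),
    total_dec_1st_sec = total_dec_1st_sec(spec),
    max_peak = max_peak(spec))
}
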