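#' Construct an audio signal
#'
#' Container for a sampled waveform: dimensionless amplitudes (nominally in
#' \eqn{[-1, 1]}) plus the sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' Duration of an audio signal in seconds
#' @param sig An `audio_signal`.
#' @return Duration in seconds (`length(samples) / sample_rate`).
#' @export
audio_duration <- function(sig) length(sig$samples) / sig$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate, audio_duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Peak-normalise an audio signal
#'
#' Rescales so that the maximum absolute sample equals `peak`. Applied once
#' at load time so that decibel features referenced to the spectrogram
#' maximum are independent of the (uncontrolled) microphone gain.
#'
#' @param sig An `audio_signal`.
#' @param peak Target peak amplitude (default 1).
#' @return A peak-normalised `audio_signal`.
#' @export
normalize_peak <- function(sig, peak = 1) {
  m <- max(abs(sig$samples))
  if (m == 0) stop("cannot peak-normalise an all-zero signal")
  audio_signal(sig$samples * (peak / m), sig$sample_rate)
}

## --- WAV (RIFF PCM) read/write -------------------------------------------
## Minimal chunk-based reader: PCM integer (16/24/32-bit) and IEEE float
## (32-bit), mono or stereo. Stereo is averaged to mono.

read_u32 <- function(raw, off) {
  sum(as.integer(raw[off + 0:3]) * c(1, 256, 65536, 16777216))
}
read_u16 <- function(raw, off) {
  sum(as.integer(raw[off + 0:1]) * c(1, 256))
}

#' Read a WAV file
#'
#' Reads a RIFF PCM WAV file (16/24/32-bit integer or 32-bit float, mono or
#' stereo). Integer samples are rescaled to \eqn{[-1, 1]} by the full-scale
#' value of the bit depth; stereo channels are averaged to mono.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file: ", path)
  pos <- 13L
  fmt <- NULL; data_off <- NULL; data_len <- NULL
  while (pos + 8L <= length(raw)) {
    cid <- rawToChar(raw[pos + 0:3])
    csz <- read_u32(raw, pos + 4L)
    body <- pos + 8L
    if (cid == "fmt ") {
      fmt <- list(audio_format = read_u16(raw, body),
                  n_channels = read_u16(raw, body + 2L),
                  sample_rate = read_u32(raw, body + 4L),
                  bits = read_u16(raw, body + 14L))
    } else if (cid == "data") {
      data_off <- body; data_len <- csz
    }
    pos <- body + csz + (csz %% 2L) # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data_off))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  bytes <- fmt$bits %/% 8L
  n_total <- data_len %/% bytes
  con <- rawConnection(raw[data_off:(data_off + data_len - 1L)])
  on.exit(close(con))
  if (fmt$audio_format == 3L) {
    if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
    x <- readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$bits == 32L) {
    x <- readBin(con, "integer", n = n_total, size = 4L,
                 endian = "little") / 2147483648
  } else if (fmt$bits == 24L) {
    b <- readBin(con, "raw", n = n_total * 3L)
    m <- matrix(as.integer(b), nrow = 3L)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else stop("unsupported PCM bit depth: ", fmt$bits)
  if (fmt$n_channels == 2L) {
    x <- (x[seq(1L, length(x), by = 2L)] + x[seq(2L, length(x), by = 2L)]) / 2
  } else if (fmt$n_channels != 1L) {
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  audio_signal(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param sig An [audio_signal()].
#' @param path Output path.
#' @param bit_depth 16, 24 or 32 (integer PCM).
#' @param float If `TRUE`, write 32-bit IEEE float samples instead.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path, bit_depth = 16L, float = FALSE) {
  x <- sig$samples
  n <- length(x)
  if (float) bit_depth <- 32L
  bytes <- bit_depth %/% 8L
  data_len <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_len)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (float) 3L else 1L); w16(1L)
  w32(sig$sample_rate); w32(sig$sample_rate * bytes)
  w16(bytes); w16(bit_depth)
  writeChar("data", con, eos = NULL); w32(data_len)
  if (float) {
    writeBin(x, con, size = 4L, endian = "little")
  } else if (bit_depth == 16L) {
    v <- pmax(pmin(round(x * 32768), 32767), -32768)
    w16(v)
  } else if (bit_depth == 32L) {
    v <- pmax(pmin(round(x * 2147483648), 2147483647), -2147483648)
    w32(v)
  } else if (bit_depth == 24L) {
    v <- pmax(pmin(round(x * 8388608), 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  } else stop("unsupported bit depth: ", bit_depth)
  invisible(path)
}

#' Resample an audio signal
#'
#' Fourier-domain resampling (spectrum truncation/zero-padding), which is
#' exact for band-limited content and preserves total in-band energy.
#'
#' @param sig An [audio_signal()].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return An `audio_signal` at `target_rate`. When `target_rate` equals the
#'   current rate the input is returned unchanged.
#' @export
resample_audio <- function(sig, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0)
    stop("`target_rate` must be a single positive number")
  if (target_rate == sig$sample_rate) return(sig)
  x <- sig$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * target_rate / sig$sample_rate)))
  X <- fft(x)
  Y <- complex(m)
  keep <- min(n %/% 2L, m %/% 2L)
  Y[1] <- X[1]
  if (keep >= 1L) {
    Y[2:(keep + 1L)] <- X[2:(keep + 1L)]
    Y[(m - keep + 1L):m] <- X[(n - keep + 1L):n]
  }
  audio_signal(Re(fft(Y, inverse = TRUE)) * (m / n) / m, target_rate)
}

#' Validate a forced-exhalation recording
#'
#' Checks duration bounds, silence (RMS below 1e-6) and clipping (fraction of
#' samples with absolute value at or above 0.999).
#'
#' @param sig An [audio_signal()].
#' @param min_s,max_s Admissible duration range in seconds.
#' @param clip_thresh Maximum tolerated clipped fraction.
#' @return A `validation_report` list: `ok`, `duration_s`, `clipped_fraction`,
#'   `silence`, `messages`.
#' @export
validate_exhalation <- function(sig, min_s = 2, max_s = 15,
                                clip_thresh = 0.01) {
  if (min_s >= max_s) stop("`min_s` must be smaller than `max_s`")
  dur <- audio_duration(sig)
  rms <- sqrt(mean(sig$samples^2))
  silence <- rms < 1e-6
  clipped <- mean(abs(sig$samples) >= 0.999)
  msgs <- character()
  if (silence) msgs <- c(msgs, "signal is silent (RMS < 1e-6)")
  if (dur < min_s) msgs <- c(msgs, sprintf("too short (%.2f s < %g s)", dur, min_s))
  if (dur > max_s) msgs <- c(msgs, sprintf("too long (%.2f s > %g s)", dur, max_s))
  if (clipped >= clip_thresh)
    msgs <- c(msgs, sprintf("clipped fraction %.3f >= %g", clipped, clip_thresh))
  structure(list(ok = dur >= min_s && dur <= max_s && !silence &&
                   clipped < clip_thresh,
                 duration_s = dur, clipped_fraction = clipped,
                 silence = silence, messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation: %s; %.2f s, clipped %.3f%s>\n",
              if (x$ok) "ok" else "rejected", x$duration_s,
              x$clipped_fraction, if (x$silence) ", silent" else ""))
  if (length(x$messages)) cat(paste0("  - ", x$messages, "\n"), sep = "")
  invisible(x)
}
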