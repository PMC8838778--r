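## Synthetic forced-exhalation audio.
##
## A blow sound is modelled as band-limited Gaussian noise (the vocal cords
## are inactive during a blow, so the source is noise shaped by the mouth):
## hot blows occupy 450-1300 Hz, cold blows 1500-4000 Hz. The amplitude is
## shaped by a flow-rate envelope whose form mimics the three canonical
## spirometry flow curves: healthy (linear rise, exponential decay),
## obstructive (faster-than-exponential decay) and restrictive
## (Weibull-density shape with reduced total capacity).

#' Pass-band of a blow type
#' @param blow_type `"cold"` or `"hot"`.
#' @return Numeric `c(low, high)` in Hz: cold 1500-4000, hot 450-1300.
#' @export
blow_band <- function(blow_type = c("cold", "hot")) {
  switch(match.arg(blow_type), cold = c(1500, 4000), hot = c(450, 1300))
}

#' Parameters of one synthetic blow
#'
#' @param blow_type `"cold"` (energy at 1500-4000 Hz) or `"hot"` (450-1300 Hz).
#' @param envelope Flow-envelope shape: `"healthy"`, `"obstructive"` or
#'   `"restrictive"`.
#' @param duration Blow duration in seconds (> 0).
#' @param peak_amplitude Peak amplitude of the result, in (0, 1].
#' @param age Age in years (label metadata).
#' @param gender 0 or 1 (label metadata).
#' @param noise_floor Amplitude of additive broadband noise.
#' @param seed Integer seed; the generated signal is a pure function of the
#'   parameters and this seed.
#' @param t_peak Time of peak flow in seconds.
#' @param lambda Exponential decay rate of the healthy envelope, 1/s.
#' @param obstr_power Exponent (> 1) on the lag in the obstructive decay.
#' @param weibull_shape,weibull_scale Shape/scale (s) of the restrictive
#'   Weibull envelope.
#' @param capacity Restrictive capacity factor in (0, 1): ratio of the
#'   restrictive envelope's time-integral to the healthy one at equal
#'   `lambda`.
#' @return A `blow_params` list.
#' @export
blow_params <- function(blow_type = c("cold", "hot"),
                        envelope = c("healthy", "obstructive", "restrictive"),
                        duration = 6, peak_amplitude = 0.9, age = 40,
                        gender = 0L, noise_floor = 0, seed = 1L,
                        t_peak = 0.2, lambda = 0.5, obstr_power = 1.6,
                        weibull_shape = 2, weibull_scale = 2.5,
                        capacity = 0.6) {
  blow_type <- match.arg(blow_type)
  envelope <- match.arg(envelope)
  if (duration <= 0) stop("`duration` must be positive")
  if (peak_amplitude <= 0 || peak_amplitude > 1)
    stop("`peak_amplitude` must be in (0, 1]")
  structure(list(blow_type = blow_type, envelope = envelope,
                 duration = duration, peak_amplitude = peak_amplitude,
                 age = age, gender = as.integer(gender),
                 noise_floor = noise_floor, seed = as.integer(seed),
                 t_peak = t_peak, lambda = lambda, obstr_power = obstr_power,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, capacity = capacity),
            class = "blow_params")
}

#' Flow-rate envelope of a forced exhalation
#'
#' Amplitude envelope in \eqn{[0, 1]} as a function of time. Shapes:
#' * `healthy`: linear rise to 1 over `[0, t_peak]`, then
#'   `exp(-lambda * (t - t_peak))`;
#' * `obstructive`: same rise, then `exp(-lambda * (t - t_peak)^p)` with
#'   `p = obstr_power > 1` (decays faster than exponentially);
#' * `restrictive`: a Weibull density reshaped so that its time-integral over
#'   `[0, duration]` equals `capacity` times the healthy integral at the same
#'   `lambda`.
#'
#' @param envelope Shape name.
#' @param t Time(s) in seconds, each within `[0, duration]`.
#' @inheritParams blow_params
#' @return Envelope value(s) in `[0, 1]`; `envelope(0) = 0` for every shape.
#' @export
flow_envelope <- function(envelope = c("healthy", "obstructive",
                                       "restrictive"),
                          t, duration = 6, t_peak = 0.2, lambda = 0.5,
                          obstr_power = 1.6, weibull_shape = 2,
                          weibull_scale = 2.5, capacity = 0.6) {
  envelope <- match.arg(envelope)
  if (any(t < 0 | t > duration))
    stop("`t` must lie within [0, duration]")
  rise <- pmin(t / t_peak, 1)
  lag <- pmax(t - t_peak, 0)
  switch(envelope,
    healthy = rise * exp(-lambda * lag),
    obstructive = rise * exp(-lambda * lag^obstr_power),
    restrictive = {
      healthy_area <- t_peak / 2 +
        (1 - exp(-lambda * (duration - t_peak))) / lambda
      norm <- pweibull(duration, weibull_shape, weibull_scale)
      capacity * healthy_area *
        dweibull(t, weibull_shape, weibull_scale) / norm
    })
}

## Evaluate an expression with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthesise one blow sound
#'
#' Seeded Gaussian white noise is passed through a zero-phase 4th-order
#' Butterworth band-pass at the blow type's pass-band, multiplied by the
#' flow envelope, mixed with `noise_floor` broadband noise and
#' peak-normalised to `peak_amplitude`. Deterministic given the seed.
#'
#' @param p A [blow_params()] object.
#' @param sample_rate Sampling rate in Hz; must be at least twice the upper
#'   pass-band edge.
#' @return An [audio_signal()].
#' @export
synth_blow <- function(p, sample_rate = 44100) {
  band <- blow_band(p$blow_type)
  if (sample_rate < 2 * band[2])
    stop("sample_rate must be >= twice the upper pass-band edge (",
         2 * band[2], " Hz)")
  n <- round(p$duration * sample_rate)
  with_seed(p$seed, {
    noise <- rnorm(n)
    bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
    x <- signal::filtfilt(bf, noise)
    tt <- (seq_len(n) - 1) / sample_rate
    env <- flow_envelope(p$envelope, tt, duration = p$duration,
                         t_peak = p$t_peak, lambda = p$lambda,
                         obstr_power = p$obstr_power,
                         weibull_shape = p$weibull_shape,
                         weibull_scale = p$weibull_scale,
                         capacity = p$capacity)
    x <- x * env
    if (p$noise_floor > 0) x <- x + p$noise_floor * rnorm(n)
    normalize_peak(audio_signal(x, sample_rate), p$peak_amplitude)
  })
}

#' Specification of a synthetic exhalation corpus
#'
#' @param n_samples Number of recordings.
#' @param age_range Age range in years, default `c(17, 67)`.
#' @param class_proportions Named proportions over envelope shapes
#'   (must sum to 1).
#' @param blow_type Blow type of the corpus (normal exhalations have a
#'   cold-blow spectrum).
#' @param lambda_slope Per-year relative increase of the envelope decay rate
#'   (older lungs empty faster relative to their capacity).
#' @param energy_slope Per-year relative decrease of the peak amplitude.
#' @param duration Blow duration in seconds.
#' @param noise_floor Additive broadband noise amplitude.
#' @param seed Corpus seed; drives ages, genders, class assignment and every
#'   per-sample signal seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_samples, age_range = c(17, 67),
                        class_proportions = c(healthy = 0.7,
                                              obstructive = 0.15,
                                              restrictive = 0.15),
                        blow_type = "cold", lambda_slope = 0.01,
                        energy_slope = 0.005, duration = 6,
                        noise_floor = 0.005, seed = 1L) {
  if (n_samples < 1) stop("`n_samples` must be at least 1")
  if (length(class_proportions) == 0)
    stop("`class_proportions` must be non-empty")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("`class_proportions` must sum to 1")
  if (!all(names(class_proportions) %in%
           c("healthy", "obstructive", "restrictive")))
    stop("unknown envelope class in `class_proportions`")
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 class_proportions = class_proportions,
                 blow_type = blow_type, lambda_slope = lambda_slope,
                 energy_slope = energy_slope, duration = duration,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a labelled synthetic corpus
#'
#' Ages are uniform over `age_range`, genders balanced, envelope classes
#' drawn at `class_proportions`. Ageing acts monotonically on the acoustics:
#' the envelope decay rate grows as `lambda * (1 + lambda_slope*(age - 17))`
#' and the peak amplitude shrinks as `(1 - energy_slope*(age - 17))`, so
#' older subjects produce faster-decaying, lower-energy blows.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [corpus_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @return A `blow_corpus`: list of records with fields `signal`
#'   ([audio_signal()]), `age`, `gender`, `envelope`, `seed`.
#' @export
synth_corpus <- function(spec, sample_rate = 44100) {
  plan <- corpus_plan(spec)
  recs <- lapply(plan, function(p)
    list(signal = synth_blow(p$params, sample_rate), age = p$params$age,
         gender = p$params$gender, envelope = p$params$envelope,
         seed = p$params$seed))
  structure(recs, class = "blow_corpus")
}

## Draw the per-sample metadata and blow parameters of a corpus without
## synthesising any audio. Deterministic given spec$seed.
corpus_plan <- function(spec) {
  n <- spec$n_samples
  with_seed(spec$seed, {
    ages <- runif(n, spec$age_range[1], spec$age_range[2])
    genders <- sample(rep(c(0L, 1L), length.out = n))
    envs <- sample(names(spec$class_proportions), n, replace = TRUE,
                   prob = spec$class_proportions)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      lam <- 0.5 * (1 + spec$lambda_slope * (ages[i] - 17))
      amp <- max(0.05, 0.9 * (1 - spec$energy_slope * (ages[i] - 17)))
      list(params = blow_params(blow_type = spec$blow_type,
                                envelope = envs[i],
                                duration = spec$duration,
                                peak_amplitude = amp, age = ages[i],
                                gender = genders[i],
                                noise_floor = spec$noise_floor,
                                seed = seeds[i], lambda = lam))
    })
  })
}

#' Generate a corpus and extract its feature table in one streaming pass
#'
#' Equivalent to `assemble_features(synth_corpus(spec))` but each blow is
#' synthesised, reduced to its 42 features and discarded before the next
#' one, so memory use stays flat for large corpora.
#'
#' @param spec A [corpus_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param cwd_cfg A [cwd_config()].
#' @return A `feature_table`, see [assemble_features()].
#' @export
synth_features <- function(spec, sample_rate = 44100,
                           cwd_cfg = cwd_config()) {
  plan <- corpus_plan(spec)
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]$params
    rec <- list(signal = synth_blow(p, sample_rate), age = p$age,
                gender = p$gender, sample_id = sprintf("s%04d", i))
    rows[[i]] <- features_one(rec, cwd_cfg = cwd_cfg)$row
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("every sample failed validation")
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("feature_table", "data.frame")
  tbl
}

#' Write a corpus to WAV files plus a labels CSV
#'
#' @param corpus A `blow_corpus` from [synth_corpus()].
#' @param dir Output directory (created if needed).
#' @param bit_depth WAV bit depth.
#' @return Path to the labels CSV (`labels.csv`: columns `file`, `age`,
#'   `gender`, `envelope`, `seed`), invisibly.
#' @export
write_corpus <- function(corpus, dir, bit_depth = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("blow_%04d.wav", seq_along(corpus))
  for (i in seq_along(corpus))
    write_wav(corpus[[i]]$signal, file.path(dir, files[i]),
              bit_depth = bit_depth)
  labels <- data.frame(file = files,
                       age = vapply(corpus, `[[`, 0, "age"),
                       gender = vapply(corpus, `[[`, 0L, "gender"),
                       envelope = vapply(corpus, `[[`, "", "envelope"),
                       seed = vapply(corpus, `[[`, 0L, "seed"))
  path <- file.path(dir, "labels.csv")
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
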