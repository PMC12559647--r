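#' Sampled audio signal with an SPL calibration convention
#'
#' `audio_signal` is the basic container of the package: a mono or stereo
#' waveform in full-scale units together with its sampling rate and the
#' calibration constant tying full scale to sound pressure level. The
#' convention used throughout is that a full-scale sinusoid (peak 1.0)
#' corresponds to `calibration` dB SPL; all experiment levels are relative,
#' so the constant itself is arbitrary but must be carried consistently.
#'
#' @param samples numeric vector (mono) or an n-by-2 matrix (stereo) of
#'   amplitudes in full-scale units. All values must be finite.
#' @param rate sampling rate in samples per second. All study stimuli use
#'   44100 Hz.
#' @param calibration dB SPL of a full-scale sinusoid (default 100).
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate = 44100, calibration = 100) {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("samples must be finite numeric values")
  if (!ncol(samples) %in% c(1L, 2L))
    stop("audio_signal supports 1 or 2 channels, got ", ncol(samples))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  structure(
    list(samples = unname(samples), rate = rate, calibration = calibration),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d channel(s), %d samples (%.3f s) @ %g Hz, level %.1f dB SPL\n",
    n_channels(x), n_samples(x), duration(x), x$rate,
    tryCatch(measure_level(x), error = function(e) NA_real_)
  ))
  invisible(x)
}

#' @export
as.matrix.audio_signal <- function(x, ...) x$samples

#' Number of samples, channel count, and duration of an audio signal
#'
#' @param x an [audio_signal].
#' @return `n_samples()` and `n_channels()` return integers; `duration()`
#'   returns seconds.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname n_samples
#' @export
duration <- function(x) nrow(x$samples) / x$rate

#' @export
plot.audio_signal <- function(x, ...) {
  t <- (seq_len(n_samples(x)) - 1) / x$rate
  graphics::matplot(t, x$samples, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "amplitude (full scale)", ...)
  invisible(x)
}

rms <- function(v) sqrt(mean(v^2))

#' Broadband level of a signal in dB SPL
#'
#' The level is derived from the pooled RMS over all channels under the
#' full-scale-sinusoid calibration: a signal whose RMS equals that of a
#' full-scale sinusoid (1/sqrt(2)) sits at `calibration` dB SPL.
#'
#' @param x an [audio_signal].
#' @return level in dB SPL.
#' @export
measure_level <- function(x) {
  r <- rms(x$samples)
  if (r == 0) stop("level of an all-zero signal is undefined")
  x$calibration + 20 * log10(r * sqrt(2))
}

#' Scale a signal to a target broadband level
#'
#' Pure scaling: the waveform shape is unchanged, only the gain is adjusted
#' so that [measure_level()] returns `level`.
#'
#' @param x an [audio_signal], not all-zero.
#' @param level target level in dB SPL.
#' @return the rescaled [audio_signal].
#' @export
set_level <- function(x, level) {
  r <- rms(x$samples)
  if (r == 0) stop("cannot set the level of an all-zero signal (undefined gain)")
  target_rms <- 10^((level - x$calibration) / 20) / sqrt(2)
  y <- x
  y$samples <- x$samples * (target_rms / r)
  y
}

#' Generate calibrated pink noise
#'
#' Stationary Gaussian noise whose power spectral density falls as 1/f
#' between `f_lo` and the Nyquist frequency, realized by FFT-domain
#' 1/sqrt(f) magnitude shaping of white Gaussian noise. The output has unit
#' RMS (before any [set_level()]) and is bit-reproducible for a fixed seed.
#'
#' @param duration_s duration in seconds (> 0).
#' @param seed integer seed.
#' @param rate sampling rate in Hz.
#' @param f_lo lower band edge in Hz (default 10).
#' @return a mono [audio_signal] with unit RMS.
#' @export
generate_pink_noise <- function(duration_s, seed, rate = 44100, f_lo = 10) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  n <- round(duration_s * rate)
  x <- with_seed(seed, stats::rnorm(n))
  f <- fft_frequencies(n, rate)
  mag <- numeric(n)
  band <- abs(f) >= f_lo
  mag[band] <- 1 / sqrt(abs(f[band]))
  y <- Re(stats::fft(stats::fft(x) * mag, inverse = TRUE)) / n
  y <- y / rms(y)
  audio_signal(y, rate = rate)
}

#' Generate a speech-like surrogate signal
#'
#' A stand-in for running female speech used as the study target: a
#' band-limited (100 Hz to 8 kHz) noise carrier with a gentle speech-like
#' spectral tilt (-6 dB/octave above 500 Hz), amplitude-modulated by a
#' positive low-frequency envelope whose modulation spectrum peaks near
#' 5 Hz. It reproduces the slow (about 5 Hz) envelope fluctuation and
#' narrowband character of speech, not its phonetic content.
#'
#' @param duration_s duration in seconds (> 0).
#' @param seed integer seed.
#' @param mod_depth modulation depth in `[0, 1]`; 0 yields a stationary
#'   band-limited carrier.
#' @param rate sampling rate in Hz.
#' @return a mono [audio_signal] with unit RMS.
#' @export
generate_speech_surrogate <- function(duration_s, seed, mod_depth = 1,
                                      rate = 44100) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  n <- round(duration_s * rate)
  z <- with_seed(seed, list(carrier = stats::rnorm(n), env = stats::rnorm(n)))
  f <- fft_frequencies(n, rate)
  af <- abs(f)
  # carrier: band-limit 100 Hz..8 kHz, -6 dB/oct tilt above 500 Hz
  mag <- numeric(n)
  band <- af >= 100 & af <= 8000
  mag[band] <- pmin(1, 500 / pmax(af[band], 500))
  carrier <- Re(stats::fft(stats::fft(z$carrier) * mag, inverse = TRUE)) / n
  # envelope: noise band-passed 2..8 Hz so its spectrum peaks near 5 Hz
  emag <- numeric(n)
  eband <- af >= 2 & af <= 8
  emag[eband] <- 1
  e <- Re(stats::fft(stats::fft(z$env) * emag, inverse = TRUE)) / n
  if (stats::sd(e) > 0) e <- e / (2.5 * stats::sd(e))  # soft-limit swing
  env <- pmax(0, 1 + mod_depth * e)
  y <- carrier * env
  y <- y / rms(y)
  audio_signal(y, rate = rate)
}

#' Generate a masker signal
#'
#' Surrogates for the two study maskers: `"speech"` is the speech-like
#' surrogate (standing in for the male-transformed ISTS nonsense-speech
#' masker) and `"music"` is a broadband pink-like noise with slow (about
#' 2 Hz) amplitude modulation standing in for the pop-music excerpt.
#'
#' @param kind `"speech"` or `"music"`.
#' @param duration_s duration in seconds.
#' @param seed integer seed.
#' @param rate sampling rate in Hz.
#' @return a mono [audio_signal] with unit RMS.
#' @export
generate_masker <- function(kind = c("speech", "music"), duration_s, seed,
                            rate = 44100) {
  kind <- match.arg(kind)
  if (kind == "speech")
    return(generate_speech_surrogate(duration_s, seed, rate = rate))
  base <- generate_pink_noise(duration_s, seed, rate = rate)
  n <- n_samples(base)
  e <- with_seed(seed + 1L, stats::rnorm(n))
  f <- fft_frequencies(n, rate)
  emag <- as.numeric(abs(f) >= 0.5 & abs(f) <= 4)
  e <- Re(stats::fft(stats::fft(e) * emag, inverse = TRUE)) / n
  if (stats::sd(e) > 0) e <- e / (3 * stats::sd(e))
  y <- base$samples[, 1] * pmax(0, 1 + 0.6 * e)
  audio_signal(y / rms(y), rate = rate)
}

#' Apply raised-cosine onset/offset ramps
#'
#' Shapes the first and last `ramp_ms` milliseconds with half-cosine
#' (raised-cosine) windows; the interior is untouched. The stimuli of the
#' study use 10-ms ramps.
#'
#' @param x an [audio_signal].
#' @param ramp_ms ramp duration in milliseconds; 0 is the identity.
#' @return the ramped [audio_signal].
#' @export
apply_raised_cosine_ramps <- function(x, ramp_ms = 10) {
  if (ramp_ms < 0) stop("ramp_ms must be non-negative")
  nr <- round(ramp_ms / 1000 * x$rate)
  if (nr == 0) return(x)
  n <- n_samples(x)
  if (2 * nr >= n) stop("ramps (2 x ", ramp_ms, " ms) exceed the signal duration")
  # gain 0 at the first sample, 1 one sample past the ramp
  w <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  g <- rep(1, n)
  g[1:nr] <- w
  g[(n - nr + 1):n] <- rev(w)
  y <- x
  y$samples <- x$samples * g
  y
}

#' Place target and maskers on the trial time axis and mix
#'
#' In `"rating"` mode the maskers start 0.5 s before the target onset (the
#' maskers are 2.5 s, the target 2 s, so all sources end together); in
#' `"detection"` mode all onsets are simultaneous. The mixture is the
#' sample-wise sum after placement, padded to the longest source.
#'
#' @param target an [audio_signal].
#' @param maskers list of [audio_signal] (possibly empty).
#' @param mode `"detection"` or `"rating"`.
#' @param masker_lead_s lead of the masker onset in rating mode (s).
#' @return the mixed [audio_signal].
#' @export
schedule_trial <- function(target, maskers = list(),
                           mode = c("detection", "rating"),
                           masker_lead_s = 0.5) {
  mode <- match.arg(mode)
  if (inherits(maskers, "audio_signal")) maskers <- list(maskers)
  for (m in maskers) {
    if (m$rate != target$rate) stop("all sources must share one sampling rate")
  }
  lead <- if (mode == "rating" && length(maskers) > 0)
    round(masker_lead_s * target$rate) else 0L
  if (mode == "rating") {
    for (m in maskers)
      if (duration(m) < duration(target))
        stop("rating-mode maskers must be at least as long as the target")
  }
  nch <- max(c(n_channels(target), vapply(maskers, n_channels, 1L)))
  total <- max(c(lead + n_samples(target),
                 vapply(maskers, n_samples, 1L)), n_samples(target))
  mix <- matrix(0, total, nch)
  add_at <- function(mix, s, at) {
    sm <- s$samples
    if (ncol(sm) == 1L && nch == 2L) sm <- cbind(sm, sm)
    idx <- at + seq_len(nrow(sm))
    mix[idx, ] <- mix[idx, ] + sm
    mix
  }
  mix <- add_at(mix, target, lead)
  for (m in maskers) mix <- add_at(mix, m, 0L)
  audio_signal(mix, rate = target$rate, calibration = target$calibration)
}

#' Signal-to-noise ratio of a target against summed maskers
#'
#' `10*log10(target power / summed masker power)`, with powers measured
#' over the target's support. A target at 63 dB SPL against two independent
#' co-located maskers of 63 dB SPL each gives about -3 dB.
#'
#' @param target an [audio_signal].
#' @param maskers non-empty list of [audio_signal] overlapping the target.
#' @return SNR in dB.
#' @export
snr_db <- function(target, maskers) {
  if (inherits(maskers, "audio_signal")) maskers <- list(maskers)
  if (length(maskers) == 0) stop("at least one masker is required")
  n <- n_samples(target)
  pt <- mean(target$samples^2)
  pm <- 0
  for (m in maskers) {
    if (m$rate != target$rate) stop("rate mismatch between target and masker")
    if (all(m$samples == 0)) stop("silent masker: SNR undefined")
    k <- min(n, n_samples(m))
    pm <- pm + mean(m$samples[seq_len(k), , drop = FALSE]^2)
  }
  10 * log10(pt / pm)
}
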