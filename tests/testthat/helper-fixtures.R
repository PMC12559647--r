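# shared fixtures and independent oracle helpers

# BRIR synthesis is the slowest operation in the suite; cache fixtures once
.brir_cache <- new.env(parent = emptyenv())

cached_brir <- function(which = c("LRL", "Large")) {
  which <- match.arg(which)
  if (is.null(.brir_cache[[which]])) {
    room <- if (which == "LRL") room_lrl() else room_large()
    .brir_cache[[which]] <- synthesize_brir(room, scene_placement(room, "0M"),
                                            "target")
  }
  .brir_cache[[which]]
}

# Hilbert envelope via the analytic signal (independent of package internals)
hilbert_envelope <- function(v) {
  n <- length(v)
  h <- numeric(n)
  h[1] <- 1
  h[2:floor(n / 2)] <- 2
  if (n %% 2 == 0) h[n / 2 + 1] <- 1
  Mod(stats::fft(stats::fft(v) * h, inverse = TRUE) / n)
}

# power in [f_lo, f_hi) from the raw periodogram, in dB
oracle_band_power_db <- function(v, rate, f_lo, f_hi) {
  n <- length(v)
  p <- Mod(stats::fft(v))^2 / n^2
  f <- (seq_len(n) - 1) * rate / n
  f[f > rate / 2] <- rate - f[f > rate / 2]
  10 * log10(sum(p[f >= f_lo & f < f_hi]))
}

# RMS gain of a filter-like transformation measured with a probe tone
probe_tone_gain_db <- function(fun, freq, rate = 44100, n = 2^15) {
  s <- audio_signal(sin(2 * pi * freq * (0:(n - 1)) / rate), rate = rate)
  y <- fun(s)
  20 * log10(sqrt(mean(y$samples^2)) / sqrt(mean(s$samples^2)))
}

# a noise-free listener for deterministic rating checks
noise_free_listener <- function(group = "ON1", seed = 99) {
  co <- generate_cohort(1, group, seed = seed)
  l <- co[[1]]
  l$rating$noise_sd <- 0
  l
}

# closed-form small-signal THD of the cubic soft clipper (weakly nonlinear
# regime): third harmonic a*A^3/4 against fundamental A - 3*a*A^3/4
small_signal_thd_percent <- function(alpha, amplitude) {
  u <- alpha * amplitude^2
  100 * (u / 4) / (1 - 3 * u / 4)
}
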