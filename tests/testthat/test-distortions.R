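test_that("spectral ripple realizes its depth, band and density", {
  # transfer function measured from a unit impulse (the filter is LTI)
  imp <- audio_signal(c(1, numeric(2^15 - 1)))
  H <- 20 * log10(Mod(stats::fft(apply_spectral_ripple(imp, 12)$samples[, 1])))
  f <- (seq_along(H) - 1) * 44100 / length(H)
  inb <- f >= 60 & f <= 14000
  expect_equal(max(H[inb]) - min(H[inb]), 12, tolerance = 0.1)
  # unity gain outside the band
  expect_lt(max(abs(H[f > 17000 & f < 22050])), 0.05)
  # gain maximum at the low band edge (first in-band bin)
  expect_equal(H[f >= 50][1], 6, tolerance = 0.2)
  # identity at zero depth
  x <- generate_pink_noise(0.5, seed = 2)
  expect_equal(apply_spectral_ripple(x, 0)$samples, x$samples,
               tolerance = 1e-10)
  expect_error(apply_spectral_ripple(x, -3), "non-negative")
})

test_that("ripple density per octave matches the printed geometry", {
  expect_equal(round(ripple_density_per_octave(10, 50, 16000), 1), 1.2)
  expect_equal(ripple_density_per_octave(8, 50, 12800), 1)
  expect_equal(ripple_density_per_octave(1, 1000, 2000), 1)
  expect_error(ripple_density_per_octave(10, 1000, 500), "f_hi > f_lo")
})

test_that("the inverse ripple filter restores the in-band signal", {
  x <- generate_pink_noise(1, seed = 3)
  y <- apply_spectral_ripple(apply_spectral_ripple(x, 12), 12, invert = TRUE)
  err_db <- 20 * log10(sqrt(mean((y$samples - x$samples)^2)) /
                       sqrt(mean(x$samples^2)))
  expect_lt(err_db, -40)  # far within 0.2 dB
})

test_that("soft saturation clips at the cubic's stationary point and stays monotone", {
  alpha <- 0.5
  xc <- saturation_clip_point(alpha)
  expect_equal(xc, 1 / sqrt(3 * alpha))
  io <- function(v) apply_saturation(audio_signal(v), alpha)$samples[, 1]
  expect_equal(io(xc), (2 / 3) * xc, tolerance = 1e-12)
  expect_equal(io(2 * xc), (2 / 3) * xc)        # held beyond the clip point
  expect_equal(io(-2 * xc), -(2 / 3) * xc)
  grid <- seq(-1.5 * xc, 1.5 * xc, length.out = 2001)
  expect_true(all(diff(io(grid)) >= -1e-12))    # monotone non-decreasing
  # identity limit for vanishing alpha
  v <- generate_pink_noise(0.1, seed = 1)$samples[, 1] * 0.1
  expect_equal(apply_saturation(audio_signal(v), 1e-8)$samples[, 1], v,
               tolerance = 1e-6)
  expect_error(apply_saturation(audio_signal(v), 0), "positive")
})

test_that("THD matches the closed-form cubic expansion in the weak regime", {
  for (alpha in c(0.01, 0.05, 0.1)) for (A in c(0.5, 1)) {
    if (alpha * A^2 < 0.2) {
      expect_equal(thd_at_peak(alpha, A)$thd_percent,
                   small_signal_thd_percent(alpha, A),
                   tolerance = 1e-3)  # 3 significant figures
    }
  }
  expect_equal(thd_at_peak(0.001, 1)$thd_percent, 0.025, tolerance = 1e-3)
  expect_error(thd_at_peak(0.1, 0), "positive")
})

test_that("THD increases with alpha at fixed amplitude", {
  A <- 1.99
  th <- vapply(seq(0.05, 0.6, by = 0.05),
               function(a) thd_at_peak(a, A)$thd_percent, 0)
  expect_true(all(diff(th) > 0))
  expect_true(all(th > 0 & th < 100))
})

test_that("a single calibrated amplitude reproduces the printed THD pairs", {
  one <- calibrate_peak_amplitude(data.frame(alpha = 0.18, thd_percent = 22.1))
  expect_equal(thd_at_peak(0.18, one$amplitude)$thd_percent, 22.1,
               tolerance = 1e-4)
  joint <- calibrate_peak_amplitude()  # all printed pairs, one amplitude
  expect_lt(joint$max_abs_residual, 0.5)
  # local optimality: perturbing the amplitude worsens the joint fit
  sse <- function(A) sum((vapply(joint$pairs$alpha, function(a)
    thd_at_peak(a, A)$thd_percent, 0) - joint$pairs$thd_percent)^2)
  expect_lt(sse(joint$amplitude), sse(joint$amplitude * 1.1))
  expect_lt(sse(joint$amplitude), sse(joint$amplitude * 0.9))
  # predicted THD is monotone in alpha over the printed alpha grid
  pred <- vapply(sort(joint$pairs$alpha), function(a)
    thd_at_peak(a, joint$amplitude)$thd_percent, 0)
  expect_true(all(diff(pred) > 0))
})

test_that("intensity distortion is a pure dB gain with unchanged spectrum", {
  x <- generate_pink_noise(1, seed = 9)
  expect_equal(apply_intensity(x, 0)$samples, x$samples)
  y <- apply_intensity(x, 4.5)
  expect_equal(sqrt(mean(y$samples^2)) / sqrt(mean(x$samples^2)),
               10^(4.5 / 20), tolerance = 1e-12)
  # normalized band powers unchanged
  for (f0 in c(100, 1000, 8000)) {
    expect_equal(
      oracle_band_power_db(y$samples[, 1], 44100, f0, 2 * f0) -
        20 * log10(sqrt(mean(y$samples^2))),
      oracle_band_power_db(x$samples[, 1], 44100, f0, 2 * f0) -
        20 * log10(sqrt(mean(x$samples^2))),
      tolerance = 1e-9)
  }
  # gains compose additively in dB
  z <- apply_intensity(apply_intensity(x, 3), 4)
  expect_equal(z$samples, apply_intensity(x, 7)$samples, tolerance = 1e-12)
  expect_error(apply_intensity(x, Inf), "finite")
})

test_that("the anchor cascade low-passes, saturates and composes", {
  x <- set_level(generate_pink_noise(1, seed = 4), 63)
  a <- make_anchor(x)   # without a room: low-pass + saturation stages
  hi <- function(v) oracle_band_power_db(v, 44100, 5000, 20000)
  expect_lt(hi(a$samples[, 1]), hi(x$samples[, 1]) - 20)
  # the saturation stage alone reproduces apply_saturation on the low-passed signal
  bf <- signal::butter(8, 3500 / 22050, type = "low")
  lp <- audio_signal(as.numeric(signal::filter(bf, x$samples[, 1])))
  expect_equal(a$samples, apply_saturation(lp, 0.55)$samples, tolerance = 1e-12)
})
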