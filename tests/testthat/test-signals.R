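test_that("pink noise has the right length, is seed-deterministic, and rejects bad input", {
  p <- generate_pink_noise(2, seed = 1)
  expect_equal(n_samples(p), 88200)
  expect_equal(duration(p), 2)
  expect_identical(p$samples, generate_pink_noise(2, seed = 1)$samples)
  expect_false(identical(p$samples, generate_pink_noise(2, seed = 2)$samples))
  expect_equal(sqrt(mean(p$samples^2)), 1, tolerance = 1e-12)
  expect_error(generate_pink_noise(0, 1), "positive")
  expect_error(generate_pink_noise(-1, 1), "positive")
})

test_that("pink noise carries equal energy per octave between 100 Hz and 10 kHz", {
  starts <- 100 * 2^(0:5)  # octaves 100..200 ... 3200..6400
  pw <- rowMeans(sapply(1:50, function(s) {
    v <- generate_pink_noise(1, seed = s)$samples[, 1]
    vapply(starts, function(f0) oracle_band_power_db(v, 44100, f0, 2 * f0), 0)
  }))
  expect_lt(max(pw) - min(pw), 1)
})

test_that("speech surrogate is narrowband with about 5 Hz envelope modulation", {
  s <- generate_speech_surrogate(4, seed = 7)
  expect_equal(n_samples(generate_speech_surrogate(1, seed = 7)), 44100)
  env <- hilbert_envelope(s$samples[, 1])
  env_lp <- stats::filter(env, rep(1 / 441, 441), sides = 2)
  env_lp <- env_lp[!is.na(env_lp)]
  es <- Mod(stats::fft(env_lp - mean(env_lp)))^2
  f <- (seq_along(es) - 1) * s$rate / length(es)
  sel <- f > 0.5 & f < 20
  peak <- f[sel][which.max(es[sel])]
  expect_gte(peak, 3)
  expect_lte(peak, 8)
  # narrowband: little energy above 10 kHz compared to the passband
  v <- s$samples[, 1]
  expect_lt(oracle_band_power_db(v, s$rate, 10000, 20000),
            oracle_band_power_db(v, s$rate, 100, 8000) - 25)
})

test_that("zero modulation depth yields a nearly stationary surrogate", {
  cv <- function(x) {
    e <- stats::filter(hilbert_envelope(x$samples[, 1]),
                       rep(1 / 2205, 2205), sides = 2)
    e <- e[!is.na(e)]
    stats::sd(e) / mean(e)
  }
  cv1 <- cv(generate_speech_surrogate(4, seed = 7))
  cv0 <- cv(generate_speech_surrogate(4, seed = 7, mod_depth = 0))
  expect_lt(cv0, 0.2 * cv1)
})

test_that("set_level calibrates, scales purely, and round-trips", {
  p <- generate_pink_noise(1, seed = 3)
  x63 <- set_level(p, 63)
  expect_equal(measure_level(x63), 63, tolerance = 1e-10)
  x66 <- set_level(x63, 66)
  expect_equal(sqrt(mean(x66$samples^2)) / sqrt(mean(x63$samples^2)),
               10^(3 / 20), tolerance = 1e-10)
  # pure scaling preserves shape
  expect_equal(x66$samples / max(abs(x66$samples)),
               x63$samples / max(abs(x63$samples)), tolerance = 1e-12)
  expect_error(set_level(audio_signal(numeric(100)), 63), "all-zero")
  expect_error(measure_level(audio_signal(numeric(10))), "undefined")
})

test_that("two independent co-located 63 dB maskers sum to about 66 dB SPL", {
  lv <- sapply(1:20, function(s) {
    m1 <- set_level(generate_pink_noise(1, seed = 100 + s), 63)
    m2 <- set_level(generate_pink_noise(1, seed = 200 + s), 63)
    measure_level(audio_signal(m1$samples + m2$samples))
  })
  expect_equal(mean(lv), 66, tolerance = 0.2)
})

test_that("raised-cosine ramps hit their window endpoints and midpoint", {
  x <- audio_signal(rep(1, 44100))
  y <- apply_raised_cosine_ramps(x, 20)  # 882-sample ramp, even length
  nr <- round(0.020 * 44100)
  expect_equal(y$samples[1, 1], 0)
  expect_equal(y$samples[nr + 1, 1], 1)
  expect_equal(y$samples[nr / 2 + 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(y$samples[n_samples(y) - nr / 2, 1], 0.5, tolerance = 1e-3)
  # interior untouched
  expect_equal(y$samples[nr + 2, 1], 1)
  expect_identical(apply_raised_cosine_ramps(x, 0)$samples, x$samples)
  expect_error(apply_raised_cosine_ramps(audio_signal(rep(1, 100)), 10),
               "exceed")
})

test_that("trial scheduling places maskers 0.5 s early in rating mode only", {
  t2 <- set_level(generate_pink_noise(2, seed = 1), 63)
  m <- set_level(generate_pink_noise(2.5, seed = 2), 63)
  mix <- schedule_trial(t2, list(m), "rating")
  expect_equal(duration(mix), 2.5)
  lead <- round(0.5 * 44100)
  # before target onset the mixture is the masker alone
  expect_equal(mix$samples[1:lead, 1], m$samples[1:lead, 1])
  expect_equal(mix$samples[lead + 1, 1], t2$samples[1, 1] + m$samples[lead + 1, 1])
  det <- schedule_trial(t2, list(m), "detection")
  expect_equal(det$samples[1, 1], t2$samples[1, 1] + m$samples[1, 1])
  expect_equal(schedule_trial(t2, list(), "rating")$samples, t2$samples)
  bad <- audio_signal(numeric(100), rate = 48000)
  expect_error(schedule_trial(t2, list(bad)), "rate")
  short <- set_level(generate_pink_noise(1, seed = 3), 60)
  expect_error(schedule_trial(t2, list(short), "rating"), "as long")
})

test_that("snr_db reproduces the -3 dB two-masker condition and simple ratios", {
  tg <- set_level(generate_pink_noise(2, seed = 11), 63)
  m1 <- set_level(generate_pink_noise(2, seed = 12), 63)
  m2 <- set_level(generate_pink_noise(2, seed = 13), 63)
  expect_equal(snr_db(tg, list(m1, m2)), -3, tolerance = 0.2)
  expect_equal(snr_db(tg, list(set_level(m1, 63))), 0, tolerance = 1e-10)
  expect_equal(snr_db(tg, list(set_level(m1, 53))), 10, tolerance = 1e-10)
  expect_error(snr_db(tg, list()), "at least one")
  expect_error(snr_db(tg, list(audio_signal(numeric(100)))), "silent")
})

test_that("set_level is idempotent and commutes with ramping to within 0.1 dB", {
  p <- generate_pink_noise(1, seed = 5)
  a <- set_level(set_level(p, 63), 63)
  expect_equal(measure_level(a), 63, tolerance = 1e-10)
  r1 <- apply_raised_cosine_ramps(set_level(p, 63), 10)
  r2 <- set_level(apply_raised_cosine_ramps(p, 10), 63)
  expect_lt(abs(measure_level(r1) - measure_level(r2)), 0.1)
})

test_that("powers of independent sources add within 0.3 dB on average", {
  dev <- sapply(1:50, function(s) {
    a <- generate_pink_noise(1, seed = 300 + s)
    b <- generate_speech_surrogate(1, seed = 600 + s)
    p_mix <- mean((a$samples + b$samples)^2)
    10 * log10(p_mix / (mean(a$samples^2) + mean(b$samples^2)))
  })
  expect_lt(abs(mean(dev)), 0.3)
})
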