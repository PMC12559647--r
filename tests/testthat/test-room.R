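test_that("room fixtures carry the printed dimensions and volumes", {
  lrl <- room_lrl()
  expect_equal(round(lrl$volume), 51)
  expect_equal(lrl$t60, 0.5)
  lg <- room_large()
  expect_equal(round(lg$volume), 102)
  expect_equal(lg$t60, 1.5)
  expect_error(room_spec(0, 1, 1, 0.5), "positive")
})

test_that("scene placement encodes the printed distances and masker gain", {
  pl <- scene_placement(room_lrl(), "2M_sep")
  expect_equal(pl$target_distance, 2.55)
  expect_equal(pl$masker_distance, 1.59)
  expect_equal(pl$masker_gain, 1.59 / 2.55)
  d <- sqrt(sum((pl$positions$target - pl$receiver)^2))
  expect_equal(d, 2.55, tolerance = 1e-9)
  pll <- scene_placement(room_large(), "2M_sep")
  expect_equal(pll$target_distance, 2)
  expect_equal(pll$masker_gain, 1)
  co <- scene_placement(room_lrl(), "2M_co")
  expect_equal(co$positions$masker_left, co$positions$target)
})

test_that("T60 estimation recovers a known exponential decay", {
  rate <- 44100
  tau <- 0.1  # amplitude time constant; energy decays 60 dB in 3*ln(10)*tau
  t <- (0:(round(1.2 * rate) - 1)) / rate
  set.seed(42)
  h <- exp(-t / tau) * rnorm(length(t))
  b <- structure(list(left = h, right = h, rate = rate,
                      direct_index = c(1L, 1L)), class = "brir")
  t60_true <- 3 * log(10) * tau
  expect_equal(estimate_t60(b), t60_true, tolerance = 0.02)
  # doubling the decay rate halves T60
  h2 <- exp(-2 * t / tau) * rnorm(length(t))
  b2 <- structure(list(left = h2, right = h2, rate = rate,
                       direct_index = c(1L, 1L)), class = "brir")
  expect_equal(estimate_t60(b2) / estimate_t60(b), 0.5, tolerance = 0.05)
  # gain invariance
  b10 <- b; b10$left <- 10 * b$left; b10$right <- 10 * b$right
  expect_equal(estimate_t60(b10), estimate_t60(b), tolerance = 1e-12)
  # a non-decaying response has no usable decay range
  bw <- structure(list(left = rnorm(4410), right = rnorm(4410), rate = rate,
                       direct_index = c(1L, 1L)), class = "brir")
  expect_error(estimate_t60(bw), "decay range")
})

test_that("synthesized BRIRs meet the target reverberation times", {
  expect_equal(estimate_t60(cached_brir("LRL")), 0.5, tolerance = 0.15)
  expect_equal(estimate_t60(cached_brir("Large")), 1.5, tolerance = 0.15)
})

test_that("the direct arrival sits at the source distance", {
  b <- cached_brir("LRL")
  expect_equal(unname(b$direct_index[1] - 1) / b$rate, 2.55 / 343,
               tolerance = 1e-3)  # within 1 ms
})

test_that("direct-sound ITD sign follows the azimuth sign", {
  room <- room_lrl()
  itd_of <- function(az) {
    pl <- scene_placement(room, "0M", target_azimuth = az)
    b <- synthesize_brir(room, pl, "target", ir_seconds = 0.06)
    # cross-correlate the direct-sound windows of the two ears
    i0 <- min(b$direct_index)
    w <- (i0 - 5):(i0 + 60)
    lags <- -20:20
    cc <- vapply(lags, function(k)
      sum(b$left[w] * b$right[w + k]), 0)
    -lags[which.max(cc)]  # >0: right ear earlier (source on the right)
  }
  expect_equal(itd_of(0), 0)
  for (az in c(8, 30, 40, 45)) expect_gt(itd_of(az), 0)
  expect_lt(itd_of(-30), 0)
  # azimuth 4 deg: sub-2-sample ITD; allow equality at integer-lag resolution
  expect_gte(itd_of(4), 1)
})

test_that("DRR handles degenerate responses and decreases with reverberation", {
  rate <- 44100
  all_direct <- structure(list(left = c(numeric(10), 1, numeric(400)),
                               right = c(numeric(10), 1, numeric(400)),
                               rate = rate, direct_index = c(11L, 11L)),
                          class = "brir")
  expect_equal(unname(compute_drr(all_direct)), c(60, 60))
  w <- round(0.0025 * rate)
  split <- structure(list(left = c(1, numeric(w), 1, numeric(200)),
                          right = c(1, numeric(w), 1, numeric(200)),
                          rate = rate, direct_index = c(1L, 1L)),
                     class = "brir")
  expect_equal(unname(compute_drr(split)), c(0, 0), tolerance = 1e-10)
  drr_lrl <- mean(compute_drr(cached_brir("LRL")))
  drr_large <- mean(compute_drr(cached_brir("Large")))
  expect_gt(drr_lrl, drr_large)
})

test_that("scene rendering convolves, shares BRIRs when co-located, and is linear", {
  room <- room_lrl()
  pl <- scene_placement(room, "2M_co")
  imp <- audio_signal(c(1, numeric(99)))
  b <- cached_brir("LRL")
  out <- render_scene(room, pl, list(target = imp), brirs = list(target = b))
  expect_equal(out$samples[seq_along(b$left), 1], b$left, tolerance = 1e-9)
  expect_equal(out$samples[seq_along(b$right), 2], b$right, tolerance = 1e-9)
  # co-located masker goes through the target's BRIR (same output)
  outm <- render_scene(room, pl, list(masker_left = imp),
                       brirs = list(target = b))
  expect_equal(outm$samples, out$samples, tolerance = 1e-9)
  # superposition: rendering a sum equals the sum of renderings
  s1 <- generate_pink_noise(0.2, seed = 21)
  s2 <- generate_speech_surrogate(0.2, seed = 22)
  both <- render_scene(room, pl, list(target = audio_signal(
    s1$samples + s2$samples)), brirs = list(target = b))
  sep <- render_scene(room, pl, list(target = s1), brirs = list(target = b))
  sep2 <- render_scene(room, pl, list(target = s2), brirs = list(target = b))
  expect_equal(both$samples, sep$samples + sep2$samples, tolerance = 1e-9)
  # energies of independent-seed sources add within 0.5 dB
  pls <- scene_placement(room, "2M_sep")
  fake <- list(target = b, masker_left = b)  # reuse one BRIR; linearity test
  e_mix <- sum(render_scene(room, pls, list(target = s1, masker_left = s2),
                            brirs = fake)$samples^2)
  e_t <- sum(render_scene(room, pls, list(target = s1), brirs = fake)$samples^2)
  e_m <- sum(render_scene(room, pls, list(masker_left = s2),
                          brirs = fake)$samples^2)
  expect_lt(abs(10 * log10(e_mix / (e_t + e_m))), 0.5)
  expect_error(render_scene(room, pls, list(target = audio_signal(
    numeric(10), rate = 48000), masker_left = s2)), "rate")
})
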