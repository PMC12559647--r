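#' Shoebox room specification
#'
#' Dimensions and target reverberation time of a rectangular room. Two
#' fixtures are provided: [room_lrl()], a living-room-lab-like room of
#' 4.97 x 3.78 x 2.71 m (51 m^3) with an average T60 of 0.5 s, and
#' [room_large()], 7.5 x 4.52 x 3 m (about 100 m^3) with a T60 of 1.5 s.
#'
#' @param length,width,height room dimensions in metres.
#' @param t60 target average reverberation time in seconds.
#' @param name label.
#' @return an object of class `room_spec` with derived `volume` (m^3) and
#'   total `surface` (m^2).
#' @export
room_spec <- function(length, width, height, t60, name = "room") {
  if (any(c(length, width, height, t60) <= 0))
    stop("room dimensions and t60 must be positive")
  structure(list(
    length = length, width = width, height = height,
    t60 = t60, name = name,
    volume = length * width * height,
    surface = 2 * (length * width + length * height + width * height)
  ), class = "room_spec")
}

#' @rdname room_spec
#' @export
room_lrl <- function() room_spec(4.97, 3.78, 2.71, 0.5, "LRL")

#' @rdname room_spec
#' @export
room_large <- function() room_spec(7.5, 4.52, 3.0, 1.5, "Large")

#' @export
print.room_spec <- function(x, ...) {
  cat(sprintf("<room_spec> %s: %.2f x %.2f x %.2f m (V = %.1f m^3), target T60 = %.2f s\n",
              x$name, x$length, x$width, x$height, x$volume, x$t60))
  invisible(x)
}

#' Receiver, target and masker placement in a room
#'
#' Builds the study scene geometry: the receiver faces along the room's
#' long axis with a 0.3-m lateral offset from the room centreline (the
#' printed scenes are asymmetric but give no coordinates); the target sits
#' at the room's target distance (2.55 m in the LRL, 2 m in the Large room)
#' at `target_azimuth` degrees (0 = frontal, positive to the right);
#' separated maskers sit at -45 and +45 degrees at the masker distance
#' (1.59 m in the LRL, 2 m in the Large room). Source/receiver heights are
#' 1.05/1.10/1.02 m in the LRL and 1.7 m in the Large room.
#'
#' @param room a [room_spec].
#' @param masker_config one of `"0M"`, `"1M_sep"`, `"2M_co"`, `"2M_sep"`.
#' @param target_azimuth azimuth of the target in degrees.
#' @return an object of class `scene_placement`.
#' @export
scene_placement <- function(room, masker_config = c("0M", "1M_sep", "2M_co", "2M_sep"),
                            target_azimuth = 0) {
  masker_config <- match.arg(masker_config)
  lrl_like <- room$t60 < 1  # LRL-style geometry vs Large-style
  d_target <- if (lrl_like) 2.55 else 2.0
  d_masker <- if (lrl_like) 1.59 else 2.0
  h <- if (lrl_like) c(receiver = 1.05, target = 1.10, masker = 1.02)
       else c(receiver = 1.7, target = 1.7, masker = 1.7)
  recv <- c(if (lrl_like) 1.2 else 1.5, room$width / 2 + 0.3, h[["receiver"]])
  # look direction +x; azimuth positive to the right (-y); the printed
  # source-receiver distances are realized as exact 3D distances
  at_azimuth <- function(az_deg, dist, height) {
    a <- az_deg * pi / 180
    horiz <- sqrt(dist^2 - (height - recv[3])^2)
    c(recv[1] + horiz * cos(a), recv[2] - horiz * sin(a), height)
  }
  pos <- list(
    target = at_azimuth(target_azimuth, d_target, h[["target"]]),
    masker_left = at_azimuth(-45, d_masker, h[["masker"]]),
    masker_right = at_azimuth(45, d_masker, h[["masker"]])
  )
  if (masker_config == "2M_co") {
    pos$masker_left <- at_azimuth(0, d_target, h[["target"]])
    pos$masker_right <- pos$masker_left
  }
  for (p in pos)
    if (any(p < 0) || p[1] > room$length || p[2] > room$width || p[3] > room$height)
      stop("source position falls outside the room")
  structure(list(
    receiver = recv, look = c(1, 0, 0), positions = pos,
    masker_config = masker_config, target_azimuth = target_azimuth,
    target_distance = d_target, masker_distance = d_masker,
    # LRL maskers are closer than the target; reduce their level to the
    # 2.55-m-equivalent level via the inverse-distance ratio
    masker_gain = if (lrl_like && masker_config %in% c("1M_sep", "2M_sep"))
      d_masker / d_target else 1
  ), class = "scene_placement")
}

SPEED_OF_SOUND <- 343
HEAD_RADIUS <- 0.0875

# Eyring average absorption coefficient hitting the target T60
eyring_absorption <- function(room) {
  a <- 1 - exp(-0.161 * room$volume / (room$surface * room$t60))
  if (a >= 1 || a <= 0) stop("target T60 unreachable for this geometry")
  a
}

# image sources of a shoebox up to a reflection order
image_sources <- function(room, src, max_order = 3) {
  dims <- c(room$length, room$width, room$height)
  ax <- lapply(1:3, function(d) {
    out <- list()
    for (q in 0:1) for (m in -2:2) {
      ord <- abs(2 * m - q)
      if (ord <= max_order)
        out[[length(out) + 1]] <- c(2 * m * dims[d] + (1 - 2 * q) * src[d], ord)
    }
    do.call(rbind, out)
  })
  g <- expand.grid(i = seq_len(nrow(ax[[1]])), j = seq_len(nrow(ax[[2]])),
                   k = seq_len(nrow(ax[[3]])))
  pos <- cbind(ax[[1]][g$i, 1], ax[[2]][g$j, 1], ax[[3]][g$k, 1])
  ord <- ax[[1]][g$i, 2] + ax[[2]][g$j, 2] + ax[[3]][g$k, 2]
  keep <- ord <= max_order
  list(pos = pos[keep, , drop = FALSE], order = ord[keep])
}

# signed lateral angle (radians, positive right) of a direction vector in
# receiver coordinates (look +x, right -y, ear axis y)
lateral_angle <- function(v) {
  asin(max(-1, min(1, -v[2] / sqrt(sum(v^2)))))
}

# first-order Brown-Duda-style head-shadow impulse response (truncated)
head_shadow_ir <- function(alpha, rate, n = 48) {
  w0 <- 2 * SPEED_OF_SOUND / HEAD_RADIUS   # rad/s
  w <- w0 / (2 * rate)
  b0 <- (alpha + w) / (1 + w)
  b1 <- (w - alpha) / (1 + w)
  a1 <- (w - 1) / (1 + w)
  h <- numeric(n)
  h[1] <- b0
  if (n > 1) {
    h[2] <- b1 - b0 * a1
    for (i in 3:n) h[i] <- -a1 * h[i - 1]
  }
  h
}

# place a kernel at a fractional sample delay into an accumulator vector
add_fractional <- function(buf, kernel, delay_samples, gain) {
  n0 <- floor(delay_samples)
  fr <- delay_samples - n0
  idx <- n0 + seq_along(kernel)
  keep <- idx >= 1 & idx + 1 <= length(buf)
  idx <- idx[keep]; kernel <- kernel[keep]
  buf[idx] <- buf[idx] + gain * (1 - fr) * kernel
  buf[idx + 1] <- buf[idx + 1] + gain * fr * kernel
  buf
}

# feedback delay network tail (stereo), unit-scale, decaying at t60
fdn_tail <- function(n_out, rate, t60, room) {
  mfp_samp <- max(64, round(4 * room$volume / room$surface / SPEED_OF_SOUND * rate))
  base <- c(1.00, 1.17, 1.31, 1.49, 1.63, 1.87, 2.03, 2.27)
  delays <- round(base * 1.8 * mfp_samp) + c(0, 1, 3, 5, 7, 11, 13, 17)
  g <- 10^(-3 * delays / (rate * t60))
  nlines <- length(delays)
  bufs <- lapply(delays, numeric)
  ptr <- rep(1L, nlines)
  outL <- numeric(n_out); outR <- numeric(n_out)
  cl <- rep(1, nlines) / sqrt(nlines)
  cr <- rep(c(1, -1), length.out = nlines) / sqrt(nlines)
  inw <- rep(1, nlines) / sqrt(nlines)
  for (t in seq_len(n_out)) {
    y <- vapply(seq_len(nlines), function(i) bufs[[i]][ptr[i]], 0)
    outL[t] <- sum(cl * y)
    outR[t] <- sum(cr * y)
    fb <- y - (2 / nlines) * sum(y)          # Householder feedback
    x_in <- if (t == 1) inw else numeric(nlines)
    for (i in seq_len(nlines)) {
      bufs[[i]][ptr[i]] <- g[i] * (fb[i] + x_in[i])
      ptr[i] <- if (ptr[i] == delays[i]) 1L else ptr[i] + 1L
    }
  }
  cbind(outL, outR)
}

#' Synthesize a binaural room impulse response
#'
#' The early part mirrors the source through the shoebox walls up to
#' third-order reflections (image-source model) with a uniform wall
#' reflection coefficient solved from Eyring's formula to meet the room's
#' target T60. Later reflections come from an 8-line feedback delay network
#' (mutually staggered delays around the room's mean free path, Householder
#' feedback, per-line decay gains tuned to the target T60), level-matched
#' to continue the image-source decay and delayed to the third-order
#' horizon. Binaural cues use a spherical-head model: interaural time
#' differences from the Woodworth formula and interaural level differences
#' from a first-order head-shadow filter per image source.
#'
#' @param room a [room_spec].
#' @param placement a [scene_placement].
#' @param source `"target"`, `"masker_left"` or `"masker_right"`.
#' @param rate sampling rate in Hz.
#' @param ir_seconds impulse-response length; default `1.25 * t60 + 0.15`.
#' @return an object of class `brir` with fields `left`, `right`, `rate`,
#'   `direct_index` (per-ear sample index of the direct arrival) and
#'   `direct_delay` (exact per-ear delay in seconds).
#' @export
synthesize_brir <- function(room, placement, source = "target", rate = 44100,
                            ir_seconds = NULL) {
  src <- placement$positions[[source]]
  if (is.null(src)) stop("unknown source label: ", source)
  if (any(src < 0) || src[1] > room$length || src[2] > room$width ||
      src[3] > room$height) stop("source position outside the room")
  if (is.null(ir_seconds)) ir_seconds <- 1.25 * room$t60 + 0.15
  n <- round(ir_seconds * rate)
  alpha_bar <- eyring_absorption(room)
  refl <- sqrt(1 - alpha_bar)
  im <- image_sources(room, src, max_order = 3)
  recv <- placement$receiver
  direct <- matrix(0, n, 2)
  early <- matrix(0, n, 2)
  arrivals <- numeric(nrow(im$pos))
  direct_delay <- c(left = NA_real_, right = NA_real_)
  r_direct <- NA_real_
  for (i in seq_len(nrow(im$pos))) {
    v <- im$pos[i, ] - recv
    r <- sqrt(sum(v^2))
    phi <- lateral_angle(v)
    itd <- (HEAD_RADIUS / SPEED_OF_SOUND) * (phi + sin(phi))
    tl <- r / SPEED_OF_SOUND + itd / 2
    tr <- r / SPEED_OF_SOUND - itd / 2
    arrivals[i] <- r / SPEED_OF_SOUND
    amp <- refl^im$order[i] / r
    hl <- head_shadow_ir(max(0.1, 1 - sin(phi)), rate)
    hr <- head_shadow_ir(max(0.1, 1 + sin(phi)), rate)
    if (im$order[i] == 0) {
      direct[, 1] <- add_fractional(direct[, 1], hl, tl * rate, amp)
      direct[, 2] <- add_fractional(direct[, 2], hr, tr * rate, amp)
      direct_delay <- c(left = tl, right = tr)
      r_direct <- r
    } else {
      early[, 1] <- add_fractional(early[, 1], hl, tl * rate, amp)
      early[, 2] <- add_fractional(early[, 2], hr, tr * rate, amp)
    }
  }
  # Late tail: onset at the third-order horizon; its energy closes the
  # diffuse-field balance E_rev/E_dir = 16*pi*r^2 / A with the Eyring
  # equivalent absorption area A = S*a/(1-a), minus the reverberant energy
  # the explicit image sources already carry.
  horizon <- max(arrivals)
  t_fdn <- min(direct_delay) + 0.6 * (horizon - min(direct_delay))
  tail <- fdn_tail(n - round(t_fdn * rate), rate, room$t60, room)
  e_dir <- sum(direct^2)
  e_early <- sum(early^2)
  area_eyring <- room$surface * alpha_bar / (1 - alpha_bar)
  e_rev_target <- e_dir * 16 * pi * r_direct^2 / area_eyring
  e_tail_target <- max(0, e_rev_target - e_early)
  e_tail_raw <- sum(tail^2)
  if (e_tail_raw > 0) tail <- tail * sqrt(e_tail_target / e_tail_raw)
  ears <- direct + early
  idx <- round(t_fdn * rate) + seq_len(nrow(tail))
  ears[idx, ] <- ears[idx, ] + tail
  structure(list(
    left = ears[, 1], right = ears[, 2], rate = rate,
    direct_index = round(direct_delay * rate) + 1L,
    direct_delay = direct_delay,
    source = source, room = room$name
  ), class = "brir")
}

#' @export
print.brir <- function(x, ...) {
  cat(sprintf("<brir> %s/%s: %d samples @ %g Hz, direct arrival L/R at %d/%d\n",
              x$room, x$source, length(x$left), x$rate,
              x$direct_index[1], x$direct_index[2]))
  invisible(x)
}

#' Reverberation time from Schroeder backward integration
#'
#' Per-ear energy decay curves are obtained by backward integration of the
#' squared impulse response; a line is fitted between -5 and -35 dB (T30)
#' and extrapolated to 60 dB. The two ears are averaged. The decay range of
#' the curve must reach at least 35 dB below the -5 dB point before the
#' final 5% of the response, otherwise an error is raised.
#'
#' @param brir a [brir] (or a plain list with `left`, `right`, `rate`).
#' @return estimated T60 in seconds.
#' @export
estimate_t60 <- function(brir) {
  one_ear <- function(h, rate) {
    edc <- rev(cumsum(rev(h^2)))
    edc_db <- 10 * log10(pmax(edc / edc[1], 1e-30))
    cut <- floor(0.95 * length(h))
    if (edc_db[cut] > -40)
      stop("insufficient decay range (< 35 dB below the -5 dB point)")
    i1 <- which(edc_db <= -5)[1]
    i2 <- which(edc_db <= -35)[1]
    tt <- (i1:i2) / rate
    fit <- stats::lm.fit(cbind(1, tt), edc_db[i1:i2])
    -60 / fit$coefficients[2]
  }
  mean(c(one_ear(brir$left, brir$rate), one_ear(brir$right, brir$rate)))
}

#' Direct-to-reverberant ratio of a binaural impulse response
#'
#' Energy in a window of +/- 2.5 ms around the direct arrival over the
#' remaining energy, in dB, per ear. A response with (numerically) no
#' reverberant energy is capped at `cap_db`.
#'
#' @param brir a [brir] with known direct-arrival indices.
#' @param window_ms half-width of the direct window in milliseconds.
#' @param cap_db cap for the degenerate all-direct case.
#' @return named vector `c(left = , right = )` in dB.
#' @export
compute_drr <- function(brir, window_ms = 2.5, cap_db = 60) {
  w <- round(window_ms / 1000 * brir$rate)
  one_ear <- function(h, d0) {
    if (d0 - w < 1 && d0 + w > length(h))
      stop("direct window exceeds the impulse response length")
    lo <- max(1, d0 - w); hi <- min(length(h), d0 + w)
    direct <- sum(h[lo:hi]^2)
    rest <- sum(h^2) - direct
    if (rest <= direct * 10^(-cap_db / 10)) return(cap_db)
    10 * log10(direct / rest)
  }
  c(left = one_ear(brir$left, brir$direct_index[1]),
    right = one_ear(brir$right, brir$direct_index[2]))
}

#' Auralize a scene: convolve sources with their BRIRs and mix
#'
#' Each mono source is convolved with the BRIR of its position and the
#' binaural results are sample-aligned and summed. In the co-located
#' masker configuration the maskers share the target's BRIR. In the LRL
#' the separated maskers (placed at 1.59 m) are attenuated by the
#' inverse-distance ratio 1.59/2.55 so that target and maskers have
#' approximately the level of a 2.55-m source.
#'
#' @param room a [room_spec].
#' @param placement a [scene_placement].
#' @param sources named list of mono [audio_signal]s; names from
#'   `"target"`, `"masker_left"`, `"masker_right"`.
#' @param brirs optional named list of precomputed [brir]s to reuse.
#' @return a 2-channel [audio_signal].
#' @export
render_scene <- function(room, placement, sources, brirs = NULL) {
  stopifnot(length(sources) >= 1, !is.null(names(sources)))
  rate <- sources[[1]]$rate
  rendered <- list()
  for (lab in names(sources)) {
    s <- sources[[lab]]
    if (s$rate != rate) stop("all sources must share one sampling rate")
    if (n_channels(s) != 1) stop("render_scene expects mono sources")
    blab <- if (placement$masker_config == "2M_co" && grepl("^masker", lab))
      "target" else lab
    br <- if (!is.null(brirs[[blab]])) brirs[[blab]]
          else synthesize_brir(room, placement, blab, rate = rate)
    gain <- if (grepl("^masker", lab)) placement$masker_gain else 1
    v <- s$samples[, 1] * gain
    rendered[[lab]] <- cbind(fft_convolve(v, br$left), fft_convolve(v, br$right))
  }
  n <- max(vapply(rendered, nrow, 1L))
  mix <- matrix(0, n, 2)
  for (m in rendered) mix[seq_len(nrow(m)), ] <- mix[seq_len(nrow(m)), ] + m
  audio_signal(mix, rate = rate, calibration = sources[[1]]$calibration)
}
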