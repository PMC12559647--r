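# internal helpers shared across modules

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# derive k reproducible child seeds (< 2^31) from one parent seed
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# signed FFT bin frequencies for an n-point transform at `rate` Hz
fft_frequencies <- function(n, rate) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * rate / n
}

# zero-phase FFT-domain filtering of a (possibly multichannel) signal with a
# magnitude response given as a function of |f|
fft_filter <- function(x, rate, magnitude_fn) {
  n <- nrow(x)
  mag <- magnitude_fn(abs(fft_frequencies(n, rate)))
  apply(x, 2, function(v) Re(stats::fft(stats::fft(v) * mag, inverse = TRUE)) / n)
}

# linear FFT convolution of a vector with a kernel (full length)
fft_convolve <- function(x, h) {
  nf <- stats::nextn(length(x) + length(h) - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(length(x) + length(h) - 1L)]
}

band_power_db <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- abs(fft_frequencies(n, rate))
  sel <- f >= f_lo & f < f_hi
  10 * log10(sum(sp[sel]) / n)
}
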