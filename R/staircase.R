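#' Configuration of a transformed up-down adaptive track
#'
#' Parameters of the 1-up/2-down, 3-interval forced-choice track used for
#' threshold estimation: the distortion amount starts at `start_value`,
#' decreases after two consecutive correct responses and increases after
#' any incorrect response; the step halves at each reversal until
#' `minimum_step` and is fixed thereafter; once at the minimum step,
#' `reversals_to_average` reversals are collected and averaged, and the
#' final threshold is the mean over `runs_per_threshold` independent runs
#' (test-retest). Step arithmetic is additive in the printed units of the
#' distortion (dB, alpha, dB, degrees) and amounts are floored at 0.
#'
#' @param start_value starting amount.
#' @param initial_step initial step size (same units).
#' @param minimum_step terminal step size (`<= initial_step`).
#' @param n_down number of consecutive correct responses per down-step
#'   (2 for the 70.7% rule).
#' @param n_intervals forced-choice intervals (3).
#' @param reversals_to_average reversals collected at minimum step (6).
#' @param runs_per_threshold independent runs averaged (2).
#' @param trial_cap abort limit per run.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(start_value, initial_step, minimum_step,
                             n_down = 2, n_intervals = 3,
                             reversals_to_average = 6, runs_per_threshold = 2,
                             trial_cap = 400) {
  if (minimum_step > initial_step) stop("minimum_step must be <= initial_step")
  if (any(c(start_value, initial_step, minimum_step) <= 0))
    stop("staircase parameters must be positive")
  structure(list(start_value = start_value, initial_step = initial_step,
                 minimum_step = minimum_step, n_down = n_down,
                 n_intervals = n_intervals,
                 reversals_to_average = reversals_to_average,
                 runs_per_threshold = runs_per_threshold,
                 trial_cap = trial_cap),
            class = "staircase_config")
}

#' Step schedules of the four distortion tracks
#'
#' The printed start value, initial step and minimum step of the adaptive
#' tracks, in the units of each distortion: ripple depth (dB): 30/5/1.5;
#' saturation (alpha): 0.82/0.2/0.035; intensity (dB): 8/2/0.4; spatial
#' (degrees): 28/4/0.5.
#'
#' @param kind `"ripple"`, `"saturation"`, `"intensity"` or `"spatial"`.
#' @return a [staircase_config].
#' @export
standard_staircase <- function(kind = c("ripple", "saturation", "intensity",
                                        "spatial")) {
  kind <- match.arg(kind)
  p <- switch(kind,
    ripple = c(30, 5, 1.5),
    saturation = c(0.82, 0.2, 0.035),
    intensity = c(8, 2, 0.4),
    spatial = c(28, 4, 0.5)
  )
  staircase_config(p[1], p[2], p[3])
}

#' Tracked percent-correct of an up-down rule
#'
#' A 1-up/n-down transformed track converges to the stimulus level where
#' the probability of `n_down` consecutive correct responses is one half:
#' `p = 0.5^(1/n_down)`, i.e. 70.7% correct for the 1-up/2-down rule.
#'
#' @param n_down consecutive-correct criterion (>= 1).
#' @return the tracked probability correct.
#' @export
staircase_convergence_probability <- function(n_down = 2) {
  if (n_down < 1) stop("n_down must be >= 1")
  0.5^(1 / n_down)
}

#' Simple logistic psychometric observer
#'
#' An observer answering a 3-AFC trial correctly with probability
#' `p(x) = guess + (1 - guess - lapse) * F((g(x) - g(threshold))/spread + c0)`
#' where `F` is the logistic function, `g` is either the identity or the
#' natural log (for ratio-like amounts), and `c0` shifts the curve so that
#' `p(threshold)` equals the 70.7% point tracked by the 1-up/2-down rule.
#'
#' @param threshold the observer's 70.7%-correct amount.
#' @param spread logistic scale in `g`-units (> 0).
#' @param transform `"identity"` or `"log"`.
#' @param guess guess rate (1/3 for 3-AFC).
#' @param lapse lapse rate in `[0, 0.05]`.
#' @return an object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(threshold, spread,
                                  transform = c("identity", "log"),
                                  guess = 1 / 3, lapse = 0) {
  transform <- match.arg(transform)
  if (spread <= 0) stop("spread must be positive")
  if (lapse < 0 || lapse > 0.05) stop("lapse must lie in [0, 0.05]")
  structure(list(threshold = threshold, spread = spread,
                 transform = transform, guess = guess, lapse = lapse),
            class = "psychometric_observer")
}

# probability correct of an observer at an amount
observer_p_correct <- function(obs, amount) {
  g <- if (obs$transform == "log") function(a) log(pmax(a, .Machine$double.xmin))
       else identity
  target_p <- staircase_convergence_probability(2)
  c0 <- log((target_p - obs$guess) / (1 - obs$lapse - target_p))
  z <- (g(amount) - g(obs$threshold)) / obs$spread + c0
  obs$guess + (1 - obs$guess - obs$lapse) * stats::plogis(z)
}

# resolve any supported listener to a p(correct | amount) function
resolve_observer <- function(listener, context = NULL) {
  if (inherits(listener, "psychometric_observer"))
    return(function(a) observer_p_correct(listener, a))
  if (inherits(listener, "simulated_listener")) {
    if (is.null(context)) stop("a context label is required for a simulated_listener")
    obs <- listener_observer(listener, context)
    return(function(a) observer_p_correct(obs, a))
  }
  stop("listener must be a psychometric_observer or simulated_listener")
}

run_one_track <- function(cfg, p_fun) {
  x <- cfg$start_value
  step <- cfg$initial_step
  n_corr <- 0L
  last_dir <- 0L
  reversals <- numeric(0)
  log_rows <- vector("list", cfg$trial_cap)
  for (trial in seq_len(cfg$trial_cap)) {
    correct <- stats::runif(1) < p_fun(x)
    n_corr <- if (correct) n_corr + 1L else 0L
    dir <- 0L
    if (!correct) dir <- 1L
    else if (n_corr == cfg$n_down) { dir <- -1L; n_corr <- 0L }
    is_rev <- dir != 0L && last_dir != 0L && dir != last_dir
    at_min <- step <= cfg$minimum_step
    log_rows[[trial]] <- c(trial, x, correct, is_rev, step)
    if (is_rev) {
      if (at_min) reversals <- c(reversals, x)
      step <- max(step / 2, cfg$minimum_step)
    }
    if (dir != 0L) {
      last_dir <- dir
      x <- max(x + dir * step, 0)
    }
    if (length(reversals) == cfg$reversals_to_average) break
  }
  trials <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  colnames(trials) <- c("trial", "amount", "correct", "reversal", "step")
  list(reversals = reversals,
       run_mean = if (length(reversals) == cfg$reversals_to_average)
         mean(reversals) else NA_real_,
       converged = length(reversals) == cfg$reversals_to_average,
       trials = as.data.frame(trials))
}

#' Run an adaptive 3-AFC staircase against a simulated listener
#'
#' Simulates the full threshold measurement: `runs_per_threshold`
#' independent 1-up/2-down tracks, each collecting
#' `reversals_to_average` reversals at the minimum step; the threshold is
#' the mean of the run means. If a track fails to collect its reversals
#' within `trial_cap` trials the estimate is reported as non-converged
#' with the partial track attached.
#'
#' @param config a [staircase_config].
#' @param listener a [psychometric_observer] or [simulated_listener].
#' @param context condition label `"kind:room"` (required for a
#'   [simulated_listener], e.g. `"ripple:LRL_2M_sep"`).
#' @param seed integer seed.
#' @return an object of class `threshold_estimate` with per-run reversal
#'   values, run means and the final `threshold`.
#' @export
run_staircase <- function(config, listener, context = NULL, seed = NULL) {
  p_fun <- resolve_observer(listener, context)
  runs <- with_seed(seed, lapply(seq_len(config$runs_per_threshold),
                                 function(i) run_one_track(config, p_fun)))
  run_means <- vapply(runs, `[[`, 0, "run_mean")
  if (anyNA(run_means))
    warning("track failed to collect its reversals within ",
            config$trial_cap, " trials; partial track attached")
  structure(list(
    runs = runs,
    run_means = run_means,
    threshold = mean(run_means),
    converged = all(vapply(runs, `[[`, TRUE, "converged")),
    context = context,
    config = config
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate>%s threshold = %.4g (runs: %s)%s\n",
              if (is.null(x$context)) "" else paste0(" [", x$context, "]"),
              x$threshold, paste(signif(x$run_means, 4), collapse = ", "),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.threshold_estimate <- function(object, ...) {
  cat(sprintf("Adaptive 1-up/%d-down %d-AFC threshold estimate\n",
              object$config$n_down, object$config$n_intervals))
  print(object)
  for (i in seq_along(object$runs)) {
    r <- object$runs[[i]]
    cat(sprintf("  run %d: %d trials, reversals at minimum step: %s\n",
                i, nrow(r$trials), paste(signif(r$reversals, 4), collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.threshold_estimate <- function(x, ...) {
  tr <- x$runs[[1]]$trials
  graphics::plot(tr$trial, tr$amount, type = "b",
                 pch = ifelse(tr$correct == 1, 19, 1),
                 xlab = "trial", ylab = "distortion amount",
                 main = "Adaptive track (run 1)", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
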