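LISTENER_GROUPS <- c("YNH", "ON1", "ON3")
DISTORTION_KINDS <- c("ripple", "saturation", "intensity", "spatial")
ROOM_CONTEXTS <- c("LRL", "Large", "LRL_2M_sep")

# amounts of ratio-like kinds live on a log scale in the observer model
KIND_TRANSFORM <- c(ripple = "log", saturation = "log",
                    intensity = "identity", spatial = "identity")
KIND_SPREAD <- c(ripple = 0.25, saturation = 0.25,
                 intensity = 0.8, spatial = 2.0)

#' Default group-level detection thresholds per distortion and context
#'
#' Mean 70.7%-correct detection thresholds, in the printed amount units of
#' each distortion, for the three listener groups (young normal-hearing
#' YNH, older very-mild-loss ON1, older moderate-loss ON3) in the three
#' study contexts (LRL, Large, LRL with two separated maskers). These are
#' the package's cohort-generator defaults; they encode the qualitative
#' group pattern of the study (masked thresholds ON3 > ON1; saturation
#' thresholds strongly increasing with hearing loss; ripple thresholds of
#' the two impaired groups similar without maskers), not any individual's
#' published data.
#'
#' @return a data.frame with columns `group`, `kind`, `room`, `threshold`.
#' @export
default_threshold_table <- function() {
  tab <- expand.grid(group = LISTENER_GROUPS, kind = DISTORTION_KINDS,
                     room = ROOM_CONTEXTS, stringsAsFactors = FALSE)
  vals <- c(
    "YNH.ripple.LRL" = 7,    "YNH.ripple.Large" = 8,    "YNH.ripple.LRL_2M_sep" = 12,
    "ON1.ripple.LRL" = 8.4,  "ON1.ripple.Large" = 9,    "ON1.ripple.LRL_2M_sep" = 15,
    "ON3.ripple.LRL" = 8.3,  "ON3.ripple.Large" = 10,   "ON3.ripple.LRL_2M_sep" = 22,
    "YNH.saturation.LRL" = 0.08, "YNH.saturation.Large" = 0.10, "YNH.saturation.LRL_2M_sep" = 0.12,
    "ON1.saturation.LRL" = 0.12, "ON1.saturation.Large" = 0.14, "ON1.saturation.LRL_2M_sep" = 0.20,
    "ON3.saturation.LRL" = 0.50, "ON3.saturation.Large" = 0.55, "ON3.saturation.LRL_2M_sep" = 0.65,
    "YNH.intensity.LRL" = 1.5, "YNH.intensity.Large" = 1.5, "YNH.intensity.LRL_2M_sep" = 2.5,
    "ON1.intensity.LRL" = 1.8, "ON1.intensity.Large" = 1.8, "ON1.intensity.LRL_2M_sep" = 3.0,
    "ON3.intensity.LRL" = 2.0, "ON3.intensity.Large" = 2.0, "ON3.intensity.LRL_2M_sep" = 5.0,
    "YNH.spatial.LRL" = 4,  "YNH.spatial.Large" = 6,  "YNH.spatial.LRL_2M_sep" = 10,
    "ON1.spatial.LRL" = 8,  "ON1.spatial.Large" = 10, "ON1.spatial.LRL_2M_sep" = 14,
    "ON3.spatial.LRL" = 13, "ON3.spatial.Large" = 16, "ON3.spatial.LRL_2M_sep" = 25
  )
  tab$threshold <- vals[paste(tab$group, tab$kind, tab$room, sep = ".")]
  tab
}

#' Construct a simulated listener
#'
#' A synthetic participant: a group label, an audiogram, a table of
#' per-(distortion, context) 70.7%-correct thresholds, a psychometric
#' spread per distortion, 3-AFC guess and lapse rates, and the parameters
#' of the rating model (score slope per doubling of the
#' distortion-to-threshold ratio, group-dependent masker term, rating
#' noise, anchor excess distance).
#'
#' @param group `"YNH"`, `"ON1"` or `"ON3"`.
#' @param audiogram an [audiogram].
#' @param thresholds named numeric vector with names `"kind:room"` (e.g.
#'   `"ripple:LRL_2M_sep"`), in printed amount units.
#' @param spreads named vector of psychometric scales per kind, in
#'   `g`-units (log for ripple/saturation, linear for intensity/spatial).
#' @param guess,lapse 3-AFC guess rate (1/3) and lapse rate.
#' @param rating list of rating-model parameters: `slope`,
#'   `masker_release` (ON1/YNH), `masker_penalty` (ON3), `noise_sd`,
#'   `anchor_extra`.
#' @param comfort_offset the listener's chosen offset (-5, 0, +5 dB).
#' @param id listener identifier.
#' @return an object of class `simulated_listener`.
#' @export
simulated_listener <- function(group, audiogram, thresholds,
                               spreads = KIND_SPREAD,
                               guess = 1 / 3, lapse = 0,
                               rating = list(slope = 18, masker_release = 10,
                                             masker_penalty = 12, noise_sd = 5,
                                             anchor_extra = 2),
                               comfort_offset = 0, id = "listener") {
  group <- match.arg(group, LISTENER_GROUPS)
  if (lapse < 0 || lapse > 0.05) stop("lapse must lie in [0, 0.05]")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(list(group = group, audiogram = audiogram,
                 thresholds = thresholds, spreads = spreads,
                 guess = guess, lapse = lapse, rating = rating,
                 comfort_offset = comfort_offset, id = id),
            class = "simulated_listener")
}

#' @export
print.simulated_listener <- function(x, ...) {
  cat(sprintf("<simulated_listener> %s (%s), PTA %.1f dB HL, comfort %+d dB, %d thresholds\n",
              x$id, x$group, pta_better_ear(x$audiogram), x$comfort_offset,
              length(x$thresholds)))
  invisible(x)
}

# threshold lookup; context = "kind:room"
listener_threshold <- function(listener, kind, room) {
  key <- paste0(kind, ":", room)
  t <- listener$thresholds[key]
  if (is.na(t)) stop("unknown context for this listener: ", key)
  unname(t)
}

# the psychometric observer implied by a listener in one context
listener_observer <- function(listener, context) {
  parts <- strsplit(context, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("context must be of the form 'kind:room'")
  kind <- parts[1]
  if (!kind %in% DISTORTION_KINDS) stop("unknown distortion kind: ", kind)
  t <- listener_threshold(listener, kind, parts[2])
  psychometric_observer(t, listener$spreads[[kind]],
                        transform = KIND_TRANSFORM[[kind]],
                        guess = listener$guess, lapse = listener$lapse)
}

#' Simulate one 3-AFC trial response
#'
#' Bernoulli draw with the listener's probability of a correct response at
#' the given distortion amount in the given context; the probability
#' equals the guess rate for vanishing amounts and 70.7% at the
#' listener's threshold.
#'
#' @param listener a [simulated_listener].
#' @param amount distortion amount in printed units.
#' @param context condition label `"kind:room"`.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   consumed).
#' @return logical: `TRUE` for a correct response.
#' @export
simulate_trial_response <- function(listener, amount, context, seed = NULL) {
  obs <- listener_observer(listener, context)
  with_seed(seed, stats::runif(1) < observer_p_correct(obs, amount))
}

# expected rating score before noise and clipping
expected_score <- function(listener, item) {
  rp <- listener$rating
  d <- if (item$level == "ref") 0
  else if (item$level == "anchor") {
    t <- listener_threshold(listener, "saturation", item$room)
    max(0, log2(0.55 / t)) + rp$anchor_extra
  } else {
    t <- listener_threshold(listener, item$kind, item$room)
    max(0, log2(item$amount / t))
  }
  score <- 100 - rp$slope * d
  if (item$masker_config != "0M") {
    score <- if (listener$group == "ON3") score - rp$masker_penalty
    else score + rp$masker_release * (1 - 2^(-d))
  }
  score
}

#' Simulate a 0-100 quality rating for one item
#'
#' The rating model maps the perceived distance of an item (in doublings
#' of its distortion amount above the listener's detection threshold) to a
#' score on the 0 ("very strong difference") to 100 ("no difference")
#' scale: `100 - slope * distance`, plus a group-dependent masker term
#' (maskers partially hide distortions for YNH/ON1, raising scores of
#' distorted items; for ON3 they lower all masked items including the
#' hidden reference), plus Gaussian rating noise. Scores are clipped to
#' `[0, 100]` and returned as integers.
#'
#' @param listener a [simulated_listener].
#' @param item a [rating_item].
#' @param seed optional integer seed.
#' @return an integer score in `[0, 100]`.
#' @export
simulate_rating <- function(listener, item, seed = NULL) {
  mu <- expected_score(listener, item)
  s <- with_seed(seed, mu + stats::rnorm(1, 0, listener$rating$noise_sd))
  as.integer(round(max(0, min(100, s))))
}

#' Generate a cohort of simulated listeners
#'
#' Builds `n_per_group` listeners per group. Audiograms are jittered
#' around the N1/N3 prototypes (flat near-0 dB HL for YNH) under the
#' 10-dB interaural-asymmetry constraint. Individual thresholds are drawn
#' around the group means of [default_threshold_table()] with lognormal
#' scatter (15%); in the masked context they are additionally coupled to
#' the listener's better-ear PTA, so that a larger hearing loss maps to
#' higher masked thresholds within each group. Comfort offsets are drawn
#' with the cohort proportions 14:8:2 over -5/0/+5 dB.
#'
#' @param n_per_group listeners per group (>= 1).
#' @param groups subset of `c("YNH", "ON1", "ON3")`.
#' @param seed integer seed.
#' @param threshold_scatter lognormal sd of individual thresholds.
#' @param pta_coupling per-dB coupling of masked thresholds to PTA.
#' @return an object of class `listener_cohort` (a list of
#'   [simulated_listener]s with attributes).
#' @export
generate_cohort <- function(n_per_group = 12, groups = c("ON1", "ON3"),
                            seed = 1, threshold_scatter = 0.15,
                            pta_coupling = 0.04) {
  stopifnot(n_per_group >= 1)
  groups <- match.arg(groups, LISTENER_GROUPS, several.ok = TRUE)
  tab <- default_threshold_table()
  proto_pta <- c(YNH = 2.5,
                 N1 = pta_better_ear(bisgaard_audiogram("N1")),
                 N3 = pta_better_ear(bisgaard_audiogram("N3")))
  n_total <- n_per_group * length(groups)
  seeds <- child_seeds(seed, 3 * n_total + 1)
  offsets <- with_seed(seeds[1], sample(c(-5, 0, 5), n_total, replace = TRUE,
                                        prob = c(14, 8, 2) / 24))
  listeners <- list()
  k <- 0
  for (g in groups) for (i in seq_len(n_per_group)) {
    k <- k + 1
    ag <- if (g == "YNH") {
      lv <- with_seed(seeds[3 * k - 1],
                      round(stats::runif(length(AUDIOMETRIC_FREQS), -5, 5) / 5) * 5)
      audiogram(lv, lv)
    } else {
      generate_audiogram(if (g == "ON1") "N1" else "N3", seeds[3 * k - 1])
    }
    pta <- pta_better_ear(ag)
    ref_pta <- proto_pta[[if (g == "YNH") "YNH" else if (g == "ON1") "N1" else "N3"]]
    gt <- tab[tab$group == g, ]
    z <- with_seed(seeds[3 * k], stats::rnorm(nrow(gt), 0, threshold_scatter))
    th <- gt$threshold * exp(z)
    masked <- gt$room == "LRL_2M_sep"
    th[masked] <- th[masked] * exp(pta_coupling * (pta - ref_pta))
    names(th) <- paste0(gt$kind, ":", gt$room)
    lapse <- with_seed(seeds[3 * k + 1], stats::runif(1, 0, 0.02))
    listeners[[k]] <- simulated_listener(
      group = g, audiogram = ag, thresholds = th, lapse = lapse,
      comfort_offset = offsets[k],
      id = sprintf("%s_%02d", g, i)
    )
  }
  structure(listeners, class = "listener_cohort",
            groups = groups, n_per_group = n_per_group, seed = seed)
}

#' @export
print.listener_cohort <- function(x, ...) {
  cat(sprintf("<listener_cohort> %d listeners (%s x %d), seed %s\n",
              length(x), paste(attr(x, "groups"), collapse = "/"),
              attr(x, "n_per_group"), attr(x, "seed")))
  invisible(x)
}

#' Extract per-listener thresholds or PTAs from a cohort
#'
#' @param cohort a `listener_cohort`.
#' @param kind distortion kind.
#' @param room context room label.
#' @return named numeric vector over listeners.
#' @export
cohort_thresholds <- function(cohort, kind, room) {
  stats::setNames(vapply(cohort, listener_threshold, 0, kind = kind, room = room),
                  vapply(cohort, `[[`, "", "id"))
}

#' @rdname cohort_thresholds
#' @export
cohort_ptas <- function(cohort) {
  stats::setNames(vapply(cohort, function(l) pta_better_ear(l$audiogram), 0),
                  vapply(cohort, `[[`, "", "id"))
}
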