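#' Signal distortion-to-detection ratio (SDDR)
#'
#' The ratio of an applied suprathreshold distortion amount to the
#' individual detection threshold in the same units. A ratio of 1 means
#' the applied distortion sits exactly at the threshold; below 1 the
#' distortion is in the below-threshold region; well above 1 it is
#' clearly suprathreshold and expected to depress quality ratings.
#'
#' @param amount applied distortion amount (vectorized).
#' @param threshold individual detection threshold, same units (> 0).
#' @return the dimensionless ratio.
#' @export
sddr <- function(amount, threshold) {
  if (any(threshold <= 0)) stop("threshold must be positive")
  amount / threshold
}

#' A single item of a quality-rating session
#'
#' @param kind distortion kind (`"ripple"`, `"saturation"`, `"intensity"`,
#'   `"spatial"`); ignored for the reference and anchor.
#' @param level `"ref"`, `"anchor"`, `"low"` or `"high"`.
#' @param amount distortion amount in printed units (`NA` for ref/anchor).
#' @param room room context (`"LRL"` or `"Large"`).
#' @param masker_config `"0M"`, `"1M_sep"`, `"2M_co"` or `"2M_sep"`.
#' @return an object of class `rating_item`.
#' @export
rating_item <- function(kind = NA_character_,
                        level = c("ref", "anchor", "low", "high"),
                        amount = NA_real_, room = "LRL",
                        masker_config = "0M") {
  level <- match.arg(level)
  if (level %in% c("low", "high")) {
    if (!kind %in% DISTORTION_KINDS) stop("unknown distortion kind: ", kind)
    if (!is.finite(amount) || amount < 0) stop("amount must be non-negative")
  }
  structure(list(kind = kind, level = level, amount = amount, room = room,
                 masker_config = masker_config,
                 id = if (level %in% c("ref", "anchor")) level
                      else paste(kind, level, sep = "_")),
            class = "rating_item")
}

#' Printed low/high distortion amounts of the rating experiments
#'
#' The amounts controlling the low and high suprathreshold distortions per
#' target: for speech, ripple 12/18 dB, saturation alpha 0.18/0.45,
#' intensity 1.5/4.5 dB, spatial 8/30 degrees; for pink noise, 2.5/5 dB,
#' 0.22/0.44, 1/4 dB, 8/30 degrees.
#'
#' @param target `"speech"` or `"noise"`.
#' @return a data.frame with columns `kind`, `level`, `amount`.
#' @export
rating_amounts <- function(target = c("speech", "noise")) {
  target <- match.arg(target)
  a <- if (target == "speech")
    c(ripple = 12, saturation = 0.18, intensity = 1.5, spatial = 8,
      ripple2 = 18, saturation2 = 0.45, intensity2 = 4.5, spatial2 = 30)
  else
    c(ripple = 2.5, saturation = 0.22, intensity = 1, spatial = 8,
      ripple2 = 5, saturation2 = 0.44, intensity2 = 4, spatial2 = 30)
  data.frame(kind = rep(DISTORTION_KINDS, 2),
             level = rep(c("low", "high"), each = 4),
             amount = unname(a), stringsAsFactors = FALSE)
}

#' Standard item set of one rating session
#'
#' One hidden reference, one anchor, and the eight kind-by-level items of
#' [rating_amounts()] for the chosen target, all in the given room and
#' masker configuration.
#'
#' @param target `"speech"` or `"noise"`.
#' @param room `"LRL"` or `"Large"`.
#' @param masker_config masker configuration label.
#' @return a list of [rating_item]s.
#' @export
standard_rating_items <- function(target = "speech", room = "LRL",
                                  masker_config = "0M") {
  am <- rating_amounts(target)
  items <- list(rating_item(level = "ref", room = room,
                            masker_config = masker_config),
                rating_item(level = "anchor", room = room,
                            masker_config = masker_config))
  for (i in seq_len(nrow(am)))
    items[[length(items) + 1]] <- rating_item(am$kind[i], am$level[i],
                                              am$amount[i], room,
                                              masker_config)
  items
}

#' Run a MUSHRA-like rating session for one simulated listener
#'
#' Scores every item with [simulate_rating()] under one seed stream. The
#' item set must contain the hidden reference; by default it must also
#' contain the anchor (`require_anchor = FALSE` relaxes this for
#' degenerate item sets).
#'
#' @param listener a [simulated_listener].
#' @param items list of [rating_item]s.
#' @param seed integer seed; test and retest sessions should use
#'   independent seeds.
#' @param tag `"test"` or `"retest"`.
#' @param require_anchor require an anchor item (default `TRUE`).
#' @return an object of class `rating_session`: a data.frame with columns
#'   `listener`, `group`, `item`, `kind`, `level`, `room`,
#'   `masker_config`, `score`, plus a `tag` attribute.
#' @export
run_rating_session <- function(listener, items, seed = NULL, tag = "test",
                               require_anchor = TRUE) {
  levels <- vapply(items, `[[`, "", "level")
  if (!"ref" %in% levels)
    stop("malformed item set: the hidden reference is missing")
  if (require_anchor && !"anchor" %in% levels)
    stop("malformed item set: the anchor is missing")
  scores <- with_seed(seed, vapply(items, function(it)
    simulate_rating(listener, it), 0L))
  out <- data.frame(
    listener = listener$id, group = listener$group,
    item = vapply(items, `[[`, "", "id"),
    kind = vapply(items, `[[`, "", "kind"),
    level = levels,
    room = vapply(items, `[[`, "", "room"),
    masker_config = vapply(items, `[[`, "", "masker_config"),
    score = scores, stringsAsFactors = FALSE
  )
  structure(out, class = c("rating_session", "data.frame"), tag = tag)
}

#' Test-retest reliability of two rating sessions
#'
#' Pearson correlation over the paired scores of two sessions covering the
#' same items. A session without score variance has no defined
#' correlation and raises an error rather than returning 0.
#'
#' @param a,b `rating_session` objects (or data.frames with `item` and
#'   `score`).
#' @return the Pearson correlation coefficient.
#' @export
test_retest_pcc <- function(a, b) {
  if (!setequal(a$item, b$item) || nrow(a) != nrow(b))
    stop("sessions must cover the same item set")
  bb <- b$score[match(a$item, b$item)]
  if (stats::sd(a$score) == 0 || stats::sd(bb) == 0)
    stop("zero score variance: correlation undefined")
  stats::cor(a$score, bb)
}

#' Correlation between detection thresholds and better-ear PTA
#'
#' Pearson correlation with its two-sided t-test between per-listener
#' detection thresholds and better-ear pure-tone averages, reported with
#' the conventional significance stars at .05 (*) and .01 (**).
#'
#' @param thresholds per-listener threshold amounts.
#' @param ptas per-listener better-ear PTAs in dB HL.
#' @return a list with `r`, `p`, `n`, `stars`.
#' @export
threshold_pta_correlation <- function(thresholds, ptas) {
  if (length(thresholds) != length(ptas)) stop("length mismatch")
  if (length(thresholds) < 4) stop("need at least 4 paired observations")
  if (stats::sd(thresholds) == 0 || stats::sd(ptas) == 0)
    stop("degenerate variance: correlation undefined")
  ct <- stats::cor.test(thresholds, ptas, method = "pearson")
  p <- ct$p.value
  list(r = unname(ct$estimate), p = p, n = length(thresholds),
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' Group-level SDDR versus quality-score summary
#'
#' Reproduces the logic linking detection thresholds to suprathreshold
#' ratings: for every group, room, distortion kind and level (low/high),
#' the mean SDDR over listeners (applied amount over individual detection
#' threshold in that room) and the mean rating score from simulated
#' sessions without maskers. Groups or cells with larger mean SDDR are
#' expected to produce lower mean scores.
#'
#' @param cohort a `listener_cohort`.
#' @param target `"speech"` or `"noise"`.
#' @param rooms rooms included (default LRL and Large).
#' @param seed integer seed for the rating sessions.
#' @return a data.frame with columns `group`, `room`, `kind`, `level`,
#'   `mean_sddr`, `mean_score`.
#' @export
sddr_rating_summary <- function(cohort, target = "speech",
                                rooms = c("LRL", "Large"), seed = 1) {
  am <- rating_amounts(target)
  seeds <- child_seeds(seed, length(cohort) * length(rooms))
  rows <- list()
  si <- 0
  sessions <- list()
  for (room in rooms) for (li in seq_along(cohort)) {
    si <- si + 1
    sessions[[si]] <- run_rating_session(
      cohort[[li]], standard_rating_items(target, room, "0M"), seeds[si])
  }
  all_scores <- do.call(rbind, sessions)
  groups <- unique(vapply(cohort, `[[`, "", "group"))
  for (g in groups) for (room in rooms) for (i in seq_len(nrow(am))) {
    members <- Filter(function(l) l$group == g, cohort)
    th <- vapply(members, listener_threshold, 0, kind = am$kind[i], room = room)
    sc <- all_scores$score[all_scores$group == g & all_scores$room == room &
                           all_scores$kind == am$kind[i] &
                           all_scores$level == am$level[i]]
    rows[[length(rows) + 1]] <- data.frame(
      group = g, room = room, kind = am$kind[i], level = am$level[i],
      mean_sddr = mean(sddr(am$amount[i], th)), mean_score = mean(sc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
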