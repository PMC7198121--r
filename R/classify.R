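# Match decisions. Scores at or above the upper cutoff are accepted,
# scores below the lower cutoff rejected, and the band in between holds
# "dubious" pairs that an iterative second round re-examines under a
# narrowed band (upper shifted down, lower shifted up, per round).

#' Cutoff configuration
#'
#' Defaults are the reference cutoffs 9400 (upper) and 8800 (lower), with a
#' symmetric shift of 100 per extra round and two rounds in total (one
#' second pass over dubious pairs).
#'
#' @param upper accept threshold; `score >= upper` is a match.
#' @param lower reject threshold; `score < lower` is a non-match. A score
#'   exactly at `lower` is dubious.
#' @param shift_step band narrowing per extra round.
#' @param max_rounds total number of rounds (1 = no second round).
#' @return list of class `cutoff_config`.
#' @export
cutoff_config <- function(upper = 9400L, lower = 8800L,
                          shift_step = 100L, max_rounds = 2L) {
  upper <- as.integer(upper); lower <- as.integer(lower)
  shift_step <- as.integer(shift_step); max_rounds <- as.integer(max_rounds)
  if (!(lower >= 0L && lower < upper && upper <= 10000L)) {
    stop("need 0 <= lower < upper <= 10000")
  }
  if (shift_step < 0L) stop("shift_step must be >= 0")
  if (max_rounds < 1L) stop("max_rounds must be >= 1")
  structure(list(upper = upper, lower = lower, shift_step = shift_step,
                 max_rounds = max_rounds), class = "cutoff_config")
}

.check_scores <- function(score) {
  if (any(is.na(score) | score < 0 | score > 10000)) {
    stop("scores must lie in [0, 10000]")
  }
}

#' Classify scores against a cutoff pair
#'
#' @param score integer vector of normalized Dice scores.
#' @param cutoffs a [cutoff_config()].
#' @return character vector: `"match"`, `"non_match"` or `"dubious"`.
#' @export
classify_scores <- function(score, cutoffs = cutoff_config()) {
  .check_scores(score)
  ifelse(score >= cutoffs$upper, "match",
         ifelse(score < cutoffs$lower, "non_match", "dubious"))
}

#' @rdname classify_scores
#' @export
classify_pair <- function(score, cutoffs = cutoff_config()) {
  stopifnot(length(score) == 1L)
  classify_scores(score, cutoffs)
}

#' Re-examine dubious pairs with shifted cutoffs
#'
#' For round r = 2..max_rounds the band narrows to
#' `upper - shift_step*(r-1)` / `lower + shift_step*(r-1)`; pairs crossing
#' the shifted thresholds are relabelled, pairs still inside the band stay
#' dubious. Earlier rounds' match/non-match labels are never revisited. If
#' shifting would invert the band, iteration stops with a warning.
#'
#' @param decisions data.frame of dubious decisions (columns `id_a`, `id_b`,
#'   `score`, `label`, `round`).
#' @param cutoffs a [cutoff_config()].
#' @return the decisions with updated `label`/`round`.
#' @export
second_round <- function(decisions, cutoffs = cutoff_config()) {
  if (nrow(decisions) && !all(decisions$label == "dubious")) {
    stop("second_round() only takes dubious pairs")
  }
  if (!nrow(decisions) || cutoffs$max_rounds < 2L) return(decisions)
  for (r in 2:cutoffs$max_rounds) {
    upper_r <- cutoffs$upper - cutoffs$shift_step * (r - 1L)
    lower_r <- cutoffs$lower + cutoffs$shift_step * (r - 1L)
    if (upper_r < lower_r) {
      warning(sprintf("round %d would invert the cutoff band; stopping", r),
              call. = FALSE)
      break
    }
    open <- decisions$label == "dubious"
    up <- open & decisions$score >= upper_r
    down <- open & decisions$score < lower_r
    decisions$label[up] <- "match"
    decisions$label[down] <- "non_match"
    decisions$round[up | down] <- r
  }
  decisions
}

#' Classify scored pairs, including the iterative second round
#'
#' @param scored data.frame with `id_a`, `id_b`, `score` (from
#'   [compare_pairs()]).
#' @param cutoffs a [cutoff_config()].
#' @return data.frame `id_a`, `id_b`, `score`, `label`, `round` (the round
#'   that decided the label; still-dubious pairs carry the last round run).
#' @export
classify_all <- function(scored, cutoffs = cutoff_config()) {
  .check_scores(scored$score)
  decisions <- data.frame(id_a = scored$id_a, id_b = scored$id_b,
                          score = as.integer(scored$score),
                          label = classify_scores(scored$score, cutoffs),
                          round = 1L, stringsAsFactors = FALSE)
  dub <- decisions$label == "dubious"
  if (any(dub) && cutoffs$max_rounds > 1L) {
    decisions[dub, ] <- second_round(decisions[dub, , drop = FALSE], cutoffs)
  }
  decisions
}

#' Greedy one-to-one deduplication of accepted matches
#'
#' Match-labelled pairs are taken in descending score order (ties broken by
#' `id_a`, then `id_b`) and a pair is kept only if neither record id has
#' already been assigned, so each record appears in at most one output pair.
#'
#' @param decisions output of [classify_all()] (or any frame with `id_a`,
#'   `id_b`, `score`, `label`).
#' @return the retained match rows.
#' @export
best_match_dedup <- function(decisions) {
  m <- decisions[decisions$label == "match", , drop = FALSE]
  if (!nrow(m)) return(m)
  m <- m[order(-m$score, m$id_a, m$id_b), , drop = FALSE]
  used_a <- new.env(hash = TRUE, parent = emptyenv())
  used_b <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!exists(m$id_a[i], envir = used_a, inherits = FALSE) &&
        !exists(m$id_b[i], envir = used_b, inherits = FALSE)) {
      keep[i] <- TRUE
      assign(m$id_a[i], TRUE, envir = used_a)
      assign(m$id_b[i], TRUE, envir = used_b)
    }
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
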