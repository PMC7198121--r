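# Pair scoring. Similarity is the Sorensen-Dice index of two bit vectors,
#   Dice = 2h / (a + b),
# with h the number of positions set in both filters and a, b the set-bit
# counts of each filter, normalized to an integer score in [0, 10000].

round_half_up <- function(x) floor(x + 0.5)

#' Sorensen-Dice similarity of two bit vectors
#'
#' @param f1,f2 equal-length 0/1 vectors.
#' @return list with `h`, `a`, `b`, `dice_raw` in `[0,1]`, `dice_norm` in
#'   `0..10000`, and `both_missing` (`TRUE` when both vectors are all-zero,
#'   in which case the score is defined as 0).
#' @export
dice <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop("filters have different lengths (", length(f1), " vs ", length(f2), ")")
  }
  f1 <- as.integer(f1); f2 <- as.integer(f2)
  h <- sum(f1 & f2)
  a <- sum(f1)
  b <- sum(f2)
  both_missing <- (a + b) == 0L
  raw <- if (both_missing) 0 else 2 * h / (a + b)
  list(h = h, a = a, b = b, dice_raw = raw,
       dice_norm = as.integer(round_half_up(raw * 10000)),
       both_missing = both_missing)
}

#' Similarity category of a normalized Dice score
#'
#' Scores partition into: exact (10000), strong (`[9000, 10000)`), weak
#' (`[8000, 9000)`) and unpaired (`[0, 8000)`).
#'
#' @param dice_norm integer vector of scores in `0..10000`.
#' @return character vector of categories.
#' @export
categorize <- function(dice_norm) {
  if (any(is.na(dice_norm) | dice_norm < 0 | dice_norm > 10000)) {
    stop("dice_norm must lie in [0, 10000]")
  }
  ifelse(dice_norm == 10000, "exact",
         ifelse(dice_norm >= 9000, "strong",
                ifelse(dice_norm >= 8000, "weak", "unpaired")))
}

# Dice pieces for a set of row pairs restricted to some columns.
.pair_dice <- function(A, B, cols) {
  X <- A[, cols, drop = FALSE]
  Y <- B[, cols, drop = FALSE]
  h <- rowSums(X * Y)
  a <- rowSums(X)
  b <- rowSums(Y)
  norm <- ifelse(a + b == 0, 0, 2 * h / (a + b)) * 10000
  list(norm = as.integer(round_half_up(norm)), present = (a + b) > 0,
       equal = rowSums(abs(X - Y)) == 0 & a + b > 0)
}

#' Score candidate pairs
#'
#' Two comparison modes:
#' \describe{
#'   \item{full}{one Dice score over the entire composite filter.}
#'   \item{hybrid}{per-attribute rules: municipality code and gender are
#'     matched exactly on their segments (equal contributes 10000, unequal
#'     0) while name, mother's name and date of birth get per-segment Dice
#'     scores with similarity categories. The combined score is the mean of
#'     the five attribute scores weighted by their bit budgets
#'     (50/50/40/20/20 by default); attributes missing on *both* sides are
#'     excluded and the weights renormalized, since shared absence is no
#'     evidence either way.}
#' }
#'
#' @param pairs data.frame with `id_a`, `id_b` (e.g. from
#'   [build_candidate_pairs()]).
#' @param filters_a,filters_b composite filter matrices from
#'   [encode_records()]; rownames must cover the pair ids.
#' @param mode `"hybrid"` or `"full"`.
#' @param weights optional named numeric vector overriding the per-attribute
#'   combination weights (hybrid mode only).
#' @return data.frame with `id_a`, `id_b`, `mode`, `score` (combined
#'   normalized Dice) and, in hybrid mode, per-attribute score/category and
#'   equality columns.
#' @export
compare_pairs <- function(pairs, filters_a, filters_b,
                          mode = c("hybrid", "full"), weights = NULL) {
  mode <- match.arg(mode)
  if (ncol(filters_a) != ncol(filters_b)) {
    stop("filter matrices have different widths")
  }
  out <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b, mode = mode,
                    stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    out$score <- integer(0)
    return(out)
  }
  ia <- match(pairs$id_a, rownames(filters_a))
  ib <- match(pairs$id_b, rownames(filters_b))
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(pairs$id_a[is.na(ia)], pairs$id_b[is.na(ib)])
    stop("no filter for record id(s): ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  A <- filters_a[ia, , drop = FALSE]
  B <- filters_b[ib, , drop = FALSE]

  if (mode == "full") {
    d <- .pair_dice(A, B, seq_len(ncol(A)))
    out$score <- d$norm
    return(out)
  }

  segs <- attr(filters_a, "segments")
  if (is.null(segs)) stop("hybrid mode needs segment metadata on the filters")
  attrs <- linkage_attributes()
  if (is.null(weights)) {
    weights <- vapply(segs, length, numeric(1))
  }
  weights <- weights[attrs]
  dice_attrs <- c("name", "mother_name", "date_of_birth")

  score_mat <- matrix(0, nrow(pairs), length(attrs),
                      dimnames = list(NULL, attrs))
  present_mat <- matrix(FALSE, nrow(pairs), length(attrs),
                        dimnames = list(NULL, attrs))
  for (a in attrs) {
    d <- .pair_dice(A, B, segs[[a]])
    present_mat[, a] <- d$present
    if (a %in% dice_attrs) {
      score_mat[, a] <- d$norm
      out[[paste0(a, "_score")]] <- d$norm
      cat_col <- rep(NA_character_, nrow(pairs))
      cat_col[d$present] <- categorize(d$norm[d$present])
      out[[paste0(a, "_category")]] <- cat_col
    } else {
      score_mat[, a] <- ifelse(d$equal, 10000, 0)
      eq_col <- rep(NA, nrow(pairs))
      eq_col[d$present] <- d$equal[d$present]
      out[[paste0(a, "_equal")]] <- eq_col
    }
  }
  w <- matrix(rep(weights, each = nrow(pairs)), nrow(pairs)) * present_mat
  denom <- rowSums(w)
  combined <- ifelse(denom == 0, 0,
                     round_half_up(rowSums(w * score_mat) / pmax(denom, 1)))
  out$score <- as.integer(combined)
  out$all_missing <- denom == 0
  out
}
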