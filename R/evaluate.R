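# Accuracy assessment against a gold standard of known true pairs.
# Specificity is computed over the evaluated pair universe (typically the
# candidate pairs plus the gold pairs), not the full cross product, where
# true negatives would dominate astronomically and make specificity
# uninformative.

pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "\x1f")

.as_pair_keys <- function(pairs) {
  if (!all(c("id_a", "id_b") %in% names(pairs))) {
    stop("pair frame needs columns id_a and id_b")
  }
  unique(pair_key(pairs$id_a, pairs$id_b))
}

#' Confusion counts of a linkage run
#'
#' @param predicted data.frame of accepted pairs (`id_a`, `id_b`).
#' @param gold data.frame of gold-standard true pairs; must be a subset of
#'   `evaluated`.
#' @param evaluated data.frame of all evaluated pairs (the pair universe).
#' @param ids_a,ids_b optional vectors of known record ids; when given,
#'   gold pairs referencing unknown ids raise an error naming them.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, gold, evaluated, ids_a = NULL, ids_b = NULL) {
  if (!is.null(ids_a) || !is.null(ids_b)) {
    bad <- c(if (!is.null(ids_a)) setdiff(gold$id_a, ids_a),
             if (!is.null(ids_b)) setdiff(gold$id_b, ids_b))
    if (length(bad)) {
      stop("gold standard references unknown record id(s): ",
           paste(utils::head(unique(bad), 10), collapse = ", "))
    }
  }
  pk <- .as_pair_keys(predicted)
  gk <- .as_pair_keys(gold)
  ek <- .as_pair_keys(evaluated)
  if (length(setdiff(gk, ek))) {
    stop("gold pairs must be contained in the evaluated pair universe")
  }
  if (length(setdiff(pk, ek))) {
    stop("predicted pairs must be contained in the evaluated pair universe")
  }
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  tn <- length(ek) - length(union(pk, gk))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Sensitivity, specificity and positive predictive value
#'
#' Undefined ratios (zero denominators) come back as `NA` with an entry in
#' `notes` explaining which metric was undefined, rather than propagating
#' NaN.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return list with `sensitivity`, `specificity`, `ppv`, `notes`.
#' @export
accuracy_metrics <- function(counts) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      list(value = NA_real_, note = paste0(what, " undefined (denominator 0)"))
    } else {
      list(value = num / den, note = NULL)
    }
  }
  sens <- ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- ratio(counts$tn, counts$tn + counts$fp, "specificity")
  ppv <- ratio(counts$tp, counts$tp + counts$fp, "ppv")
  list(sensitivity = sens$value, specificity = spec$value, ppv = ppv$value,
       notes = c(sens$note, spec$note, ppv$note))
}

#' ROC sweep over Dice thresholds with best-cutoff selection
#'
#' For each threshold t in the grid, every scored pair with `score >= t` is
#' accepted, and the point (t, sensitivity, false-positive rate) recorded.
#' The best cutoff maximizes Youden's J = sensitivity + specificity - 1
#' (ties broken toward the higher threshold); alternatively it maximizes
#' PPV subject to a sensitivity floor.
#'
#' @param scored data.frame with `id_a`, `id_b`, `score`; the scored pairs
#'   are the evaluation universe, so every pair has a gold label.
#' @param gold data.frame of true pairs (`id_a`, `id_b`); must contain at
#'   least one pair present among the scored pairs.
#' @param grid numeric vector of thresholds (default 8000 to 10000 by 100).
#' @param criterion `"youden"` or `"ppv_floor"`.
#' @param sens_floor minimum sensitivity for `"ppv_floor"`.
#' @return list with `roc` (data.frame `threshold`, `sensitivity`, `fpr`),
#'   `best_cutoff`, `best_cutoff_criterion`.
#' @export
roc_sweep <- function(scored, gold, grid = seq(8000L, 10000L, by = 100L),
                      criterion = c("youden", "ppv_floor"), sens_floor = 0.9) {
  criterion <- match.arg(criterion)
  .check_scores(scored$score)
  truth <- pair_key(scored$id_a, scored$id_b) %in% .as_pair_keys(gold)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L) {
    stop("no gold-standard true pairs among the scored pairs; ROC undefined")
  }
  grid <- sort(unique(as.integer(grid)))
  pts <- vapply(grid, function(t) {
    acc <- scored$score >= t
    tp <- sum(acc & truth)
    fp <- sum(acc & !truth)
    c(sens = tp / n_pos,
      fpr = if (n_neg == 0L) 0 else fp / n_neg,
      ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp))
  }, numeric(3))
  roc <- data.frame(threshold = grid, sensitivity = pts["sens", ],
                    fpr = pts["fpr", ])
  if (criterion == "youden") {
    j <- roc$sensitivity - roc$fpr
    best <- grid[max(which(j == max(j)))]
  } else {
    ok <- roc$sensitivity >= sens_floor & !is.na(pts["ppv", ])
    if (!any(ok)) {
      stop("no threshold reaches the sensitivity floor ", sens_floor)
    }
    ppv_ok <- ifelse(ok, pts["ppv", ], -Inf)
    best <- grid[max(which(ppv_ok == max(ppv_ok)))]
  }
  list(roc = roc, best_cutoff = as.integer(best),
       best_cutoff_criterion = criterion)
}

#' Full accuracy report
#'
#' Confusion counts, the three headline metrics and (when scores are
#' supplied) the ROC sweep with best-cutoff selection.
#'
#' @inheritParams confusion
#' @param scored optional scored pair frame for the ROC sweep.
#' @param ... passed to [roc_sweep()].
#' @return list of class `accuracy_report`.
#' @export
accuracy_report <- function(predicted, gold, evaluated, scored = NULL,
                            ids_a = NULL, ids_b = NULL, ...) {
  counts <- confusion(predicted, gold, evaluated, ids_a, ids_b)
  metrics <- accuracy_metrics(counts)
  roc <- if (!is.null(scored) && nrow(gold)) roc_sweep(scored, gold, ...)
  structure(list(counts = counts, metrics = metrics, roc = roc),
            class = "accuracy_report")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
print.accuracy_report <- function(x, ...) {
  print(x$counts)
  m <- x$metrics
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s\n",
              fmt(m$sensitivity), fmt(m$specificity), fmt(m$ppv)))
  if (!is.null(x$roc)) {
    cat(sprintf("best cutoff %d (%s)\n", x$roc$best_cutoff,
                x$roc$best_cutoff_criterion))
  }
  invisible(x)
}
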