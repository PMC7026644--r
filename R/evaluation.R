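#' Confusion counts against a reference structure
#'
#' Compares a predicted pair set with a reference over the universe of
#' all `C(L, 2)` unordered position pairs: TP are predicted reference
#' pairs, FP predicted non-reference pairs, FN missed reference pairs
#' and TN everything else, so `tp + fp + tn + fn = C(L, 2)`.
#' Noncanonical reference pairs count as positives.
#'
#' @param predicted,reference Pair tibbles (columns `i`, `j`).
#' @param L Sequence length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, reference, L) {
  pk <- pair_keys(predicted, L)
  rk <- pair_keys(reference, L)
  n_univ <- choose(L, 2)
  tp <- length(intersect(pk, rk))
  fp <- length(setdiff(pk, rk))
  fn <- length(setdiff(rk, pk))
  tibble(tp = tp, fp = fp, tn = n_univ - tp - fp - fn, fn = fn)
}

pair_keys <- function(pairs, L) {
  if (nrow(pairs) == 0) return(integer(0))
  i <- pmin(pairs$i, pairs$j)
  j <- pmax(pairs$i, pairs$j)
  if (any(i < 1 | j > L)) stop("pair position outside [1, L]")
  if (any(i == j)) stop("pair with i == j")
  unique((i - 1) * L + j)
}

counts_vec <- function(counts) {
  unlist(counts[c("tp", "fp", "tn", "fn")])
}

#' Binary-classification metrics for base-pair prediction
#'
#' Matthews correlation coefficient, sensitivity (recall) and precision
#' from confusion counts:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, \quad
#'  Sens = \frac{TP}{TP+FN}, \quad Prec = \frac{TP}{TP+FP}.}
#' A metric whose denominator is zero is reported as 0 (with a message).
#'
#' @param counts A one-row data frame or named list with `tp`, `fp`,
#'   `tn`, `fn` (e.g. from [confusion_counts()]).
#' @return A numeric scalar.
#' @export
mcc <- function(counts) {
  v <- counts_vec(counts)
  den <- (v["tp"] + v["fp"]) * (v["tp"] + v["fn"]) *
    (v["tn"] + v["fp"]) * (v["tn"] + v["fn"])
  if (den == 0) {
    message("MCC denominator is zero; returning 0")
    return(0)
  }
  unname((v["tp"] * v["tn"] - v["fp"] * v["fn"]) / sqrt(den))
}

#' @rdname mcc
#' @export
sensitivity <- function(counts) {
  v <- counts_vec(counts)
  if (v["tp"] + v["fn"] == 0) {
    message("no reference pairs; sensitivity reported as 0")
    return(0)
  }
  unname(v["tp"] / (v["tp"] + v["fn"]))
}

#' @rdname mcc
#' @export
precision <- function(counts) {
  v <- counts_vec(counts)
  if (v["tp"] + v["fp"] == 0) {
    message("no predicted pairs; precision reported as 0")
    return(0)
  }
  unname(v["tp"] / (v["tp"] + v["fp"]))
}

# Ranked positives/negatives for threshold sweeps: distinct score values
# in decreasing order with cumulative tp/fp when predicting
# "score >= cutoff". Unscored pairs are implicitly at -Inf (never
# predicted at any finite cutoff).
score_sweep <- function(position_scores, reference, L) {
  if (nrow(reference) == 0) stop("reference structure has no pairs")
  if (nrow(position_scores) == 0) stop("no scored position pairs")
  sk <- pair_keys(position_scores, L)
  if (length(sk) != nrow(position_scores)) {
    stop("duplicated position pair in scores")
  }
  rk <- pair_keys(reference, L)
  val <- if ("ps" %in% names(position_scores)) {
    position_scores$ps
  } else if ("score" %in% names(position_scores)) {
    position_scores$score
  } else position_scores[[3]]
  o <- order(val, decreasing = TRUE)
  val <- val[o]
  is_pos <- sk[o] %in% rk
  grp <- !duplicated(val)           # first row of each tied block
  cum_tp <- cumsum(is_pos)
  cum_fp <- cumsum(!is_pos)
  last <- c(which(grp)[-1] - 1, length(val))  # last row of each block
  tibble(threshold = val[grp], tp = cum_tp[last], fp = cum_fp[last])
}

#' Precision-recall curve and area under it
#'
#' Pairs are ranked by score (descending); every distinct score value is
#' a cutoff predicting the pairs scoring at or above it, with ties
#' grouped at one threshold and unscored pairs ranked below all scored
#' pairs. The area is the trapezoid over `(recall, precision)` with the
#' curve anchored horizontally from recall 0 at the first threshold's
#' precision. The precision-recall view is preferred over ROC because
#' base pairs are a rare positive class (about 50 unpaired combinations
#' per true pair).
#'
#' @param position_scores Tibble `i, j` plus a score column (`ps`,
#'   `score`, or the third column).
#' @param reference Reference pair tibble.
#' @param L Sequence length.
#' @return A list with `curve` (tibble `threshold, recall, precision`)
#'   and `auc_pr`.
#' @export
pr_curve <- function(position_scores, reference, L) {
  sw <- score_sweep(position_scores, reference, L)
  P <- nrow(reference)
  recall <- sw$tp / P
  prec <- sw$tp / (sw$tp + sw$fp)
  curve <- tibble(threshold = sw$threshold, recall = recall,
                  precision = prec)
  r <- c(0, recall)
  p <- c(prec[1], prec)
  auc <- sum(diff(r) * (head(p, -1) + p[-1]) / 2)
  list(curve = curve, auc_pr = auc)
}

#' Threshold maximizing the Matthews correlation coefficient
#'
#' Scans every distinct score value as a cutoff (pair predicted iff its
#' score is at least the cutoff) and returns the cutoff with maximal
#' MCC; ties are broken toward the larger cutoff (fewer predictions).
#' Sensitivity and precision at the same cutoff accompany the counts.
#'
#' @inheritParams pr_curve
#' @return A list with `threshold`, `counts` (one-row tibble), `mcc`,
#'   `sensitivity`, `precision`.
#' @export
max_mcc_threshold <- function(position_scores, reference, L) {
  sw <- score_sweep(position_scores, reference, L)
  P <- nrow(reference)
  n_univ <- choose(L, 2)
  mccs <- vapply(seq_len(nrow(sw)), function(k) {
    cnt <- tibble(tp = sw$tp[k], fp = sw$fp[k],
                  fn = P - sw$tp[k],
                  tn = n_univ - sw$tp[k] - sw$fp[k] - (P - sw$tp[k]))
    suppressMessages(mcc(cnt))
  }, numeric(1))
  best <- which.max(mccs)  # first index = largest cutoff on ties
  counts <- tibble(tp = sw$tp[best], fp = sw$fp[best],
                   fn = P - sw$tp[best],
                   tn = n_univ - sw$tp[best] - sw$fp[best] -
                     (P - sw$tp[best]))
  list(threshold = sw$threshold[best], counts = counts,
       mcc = mccs[best],
       sensitivity = suppressMessages(sensitivity(counts)),
       precision = suppressMessages(precision(counts)))
}
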