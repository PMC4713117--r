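#' Confusion matrix for binary predictions
#'
#' Counts outcomes against the positive class coded 1.
#'
#' @param y_true observed labels, each 0 or 1.
#' @param y_pred predicted labels, each 0 or 1, same length.
#' @return A `gaeoc_confusion` object with integer fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 1, 0, 0), c(1, 0, 1, 1, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length (", length(y_true),
         " vs ", length(y_pred), ")")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels and predictions must be binary (0/1)")
  }
  structure(
    list(
      tp = sum(y_true == 1L & y_pred == 1L),
      fp = sum(y_true == 0L & y_pred == 1L),
      tn = sum(y_true == 0L & y_pred == 0L),
      fn = sum(y_true == 1L & y_pred == 0L)
    ),
    class = "gaeoc_confusion"
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A `gaeoc_confusion` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "gaeoc_confusion")
}

#' @export
print.gaeoc_confusion <- function(x, ...) {
  cat("2x2 confusion matrix (positive class = 1)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a
#' correlation-style score in \[-1, 1\] that uses all four cells of the
#' confusion matrix and is robust to class imbalance. When any factor of
#' the denominator is zero (e.g. a one-class predictor) the score is 0 by
#' convention, which is also what a trivial majority-class predictor earns.
#'
#' The numerator is computed in integer-exact double arithmetic and only
#' the denominator takes a floating square root, so large counts do not
#' lose precision.
#'
#' @param cm a `gaeoc_confusion` object (or list with tp/fp/tn/fn).
#' @return MCC in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(tp = 45, fp = 0, tn = 45, fn = 0))  # 1
#' mcc(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5))   # 0 by convention
#' @export
mcc <- function(cm) {
  tp <- as.double(cm$tp); fp <- as.double(cm$fp)
  tn <- as.double(cm$tn); fn <- as.double(cm$fn)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")
  d1 <- tp + fp; d2 <- tp + fn; d3 <- tn + fp; d4 <- tn + fn
  if (d1 == 0 || d2 == 0 || d3 == 0 || d4 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d1 * d2 * d3 * d4)
}

#' Standard classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F-measure and MCC. Ratios with a zero
#' denominator are reported as 0 and listed in the `undefined` field
#' rather than as NaN, so degenerate predictors still yield a full record.
#'
#' @param cm a `gaeoc_confusion` object.
#' @return List with `accuracy`, `precision`, `recall`, `f_measure`,
#'   `mcc`, and `undefined` (character vector of flagged ratios).
#' @export
classification_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")
  undefined <- character()
  safe <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f <- safe(2 * precision * recall, precision + recall, "f_measure")
  list(
    accuracy = (tp + tn) / n,
    precision = precision,
    recall = recall,
    f_measure = f,
    mcc = mcc(cm),
    undefined = undefined
  )
}

#' Unweighted majority vote over one sample's member predictions
#'
#' Returns 1 when the positive votes strictly exceed half the members, 0
#' when strictly below, and draws uniformly from \{0, 1\} on an exact tie
#' (only possible for an even number of voters). Tie draws come from an
#' explicit stream so runs are reproducible.
#'
#' @param votes binary vector, one vote per ensemble member.
#' @param tie_rng a [rng_stream()] used only on exact ties.
#' @return 0 or 1.
#' @export
majority_vote <- function(votes, tie_rng) {
  if (length(votes) == 0L) stop("empty vote vector")
  votes <- as.integer(votes)
  if (!all(votes %in% c(0L, 1L))) stop("votes must be binary (0/1)")
  k <- length(votes)
  s <- sum(votes)
  if (s * 2L > k) return(1L)
  if (s * 2L < k) return(0L)
  as.integer(stream_runif(tie_rng) < 0.5)
}

#' Majority-vote predictions of an ensemble over many samples
#'
#' Applies the unweighted majority vote elementwise across the selected
#' members' prediction vectors. Ties are broken per sample from `tie_rng`,
#' drawn in sample order.
#'
#' @param member_ids character (or integer) ids naming entries of
#'   `per_member_predictions`.
#' @param per_member_predictions named list (or matrix rows) of equal-length
#'   binary prediction vectors.
#' @param tie_rng a [rng_stream()].
#' @return Integer vector of 0/1 ensemble predictions.
#' @export
ensemble_predict <- function(member_ids, per_member_predictions, tie_rng) {
  if (length(member_ids) == 0L) stop("empty ensemble")
  if (is.matrix(per_member_predictions)) {
    pm <- per_member_predictions[member_ids, , drop = FALSE]
  } else {
    missing <- setdiff(as.character(member_ids), names(per_member_predictions))
    if (length(missing)) {
      stop("missing member predictions: ", paste(missing, collapse = ", "))
    }
    vecs <- per_member_predictions[as.character(member_ids)]
    lens <- lengths(vecs)
    if (length(unique(lens)) != 1L) stop("member prediction lengths differ")
    pm <- do.call(rbind, vecs)
  }
  vote_matrix(pm, tie_rng)
}

# Scalar MCC from raw counts; hot path for fitness evaluation.
mcc_counts <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Vectorised vote over a members x samples 0/1 matrix; ties resolved in
# column order so the tie stream is consumed deterministically.
vote_matrix <- function(pm, tie_rng) {
  k <- nrow(pm)
  s <- colSums(pm)
  out <- integer(ncol(pm))
  out[s * 2 > k] <- 1L
  ties <- which(s * 2 == k)
  if (length(ties)) {
    out[ties] <- as.integer(stream_runif(tie_rng, length(ties)) < 0.5)
  }
  out
}
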