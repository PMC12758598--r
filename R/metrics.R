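#' Confusion counts at a threshold
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 calls.
#' @return list with tp, fp, tn, fn.
#' @export
confusion_counts <- function(y_true, y_pred) {
  list(tp = sum(y_true == 1L & y_pred == 1L),
       fp = sum(y_true == 0L & y_pred == 1L),
       tn = sum(y_true == 0L & y_pred == 0L),
       fn = sum(y_true == 1L & y_pred == 0L))
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) with mid-ranks for ties; equals the
#' probability that a random positive outscores a random negative, counting
#' ties as 1/2.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_prob scores.
#' @return AUROC in [0, 1], or NA with a warning if one class is absent.
#' @export
auroc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration (average precision): sum over descending score
#' thresholds of precision times the recall increment, with tied scores
#' handled as a single threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1], or NA with a warning if one class is absent.
#' @export
auprc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1L)
  if (n1 == 0L || all(y_true == 1L)) {
    warning("AUPRC undefined with a single class")
    return(NA_real_)
  }
  o <- order(y_prob, decreasing = TRUE)
  yt <- y_true[o]; sc <- y_prob[o]
  tp <- cumsum(yt == 1L)
  fp <- cumsum(yt == 0L)
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Binary classification metrics
#'
#' Computes accuracy, sensitivity (recall of class 1), specificity, Matthews
#' correlation coefficient, AUROC and AUPRC. MCC is defined as
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))` and reported as 0
#' when any denominator factor is 0. With a single-class `y_true`, AUROC and
#' AUPRC are reported as NA with a warning.
#'
#' @param y_true 0/1 labels.
#' @param y_prob scores in [0, 1].
#' @param threshold call threshold on the score (default 0.5, calls use >=).
#' @return named list of metrics plus the confusion counts.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  assert_that(all(y_true %in% c(0L, 1L)), "y_true must be 0/1")
  assert_that(all(y_prob >= 0 & y_prob <= 1), "y_prob must be in [0, 1]")
  y_pred <- as.integer(y_prob >= threshold)
  cc <- confusion_counts(y_true, y_pred)
  n <- length(y_true)
  mcc_den <- prod(sqrt(c(cc$tp + cc$fp, cc$tp + cc$fn, cc$tn + cc$fp, cc$tn + cc$fn)))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(cc$tp) * cc$tn - as.numeric(cc$fp) * cc$fn) / mcc_den
  single <- length(unique(y_true)) < 2L
  list(
    accuracy = (cc$tp + cc$tn) / n,
    sensitivity = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    specificity = if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_,
    mcc = mcc,
    auroc = if (single) { warning("AUROC undefined with a single class"); NA_real_ }
            else auroc(y_true, y_prob),
    auprc = if (single) NA_real_ else auprc(y_true, y_prob),
    confusion = cc
  )
}
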