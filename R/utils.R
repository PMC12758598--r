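#' @importFrom stats rnorm runif sd var predict quantile
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

#' Stratified train/test split indices
#'
#' Splits sample indices into a train and holdout set while preserving the
#' class ratio within one sample per class.
#'
#' @param y binary label vector (0/1).
#' @param ratio fraction of samples assigned to the train set.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with integer index vectors `train` and `holdout`.
#' @keywords internal
stratified_split <- function(y, ratio, seed) {
  assert_that(ratio > 0 && ratio < 1, "split ratio must be in (0, 1)")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop2("stratified split requires both classes present")
  withr::with_seed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(y == cl)
      n_tr <- round(length(idx) * ratio)
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
  })
  holdout <- setdiff(seq_along(y), train)
  if (length(holdout) == 0L) stop2("holdout set is empty; lower the split ratio")
  list(train = train, holdout = holdout)
}

#' Stratified k-fold assignment
#'
#' @param y binary label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, one per sample; every fold
#'   contains both classes or an error is raised.
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  assert_that(k >= 2, "need at least 2 folds")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) stop2("class ", cl, " has fewer samples (", length(idx),
                                 ") than folds (", k, ")")
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  for (f in seq_len(k)) {
    if (length(unique(y[folds == f])) < 2L)
      stop2("fold ", f, " contains a single class; reduce folds or rebalance")
  }
  folds
}

# Derive a stream-specific child seed from a base seed; keeps values < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}
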