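# Weighted regression trees and tree ensembles, implemented in vectorized R.
# These back the gradient-boosting level-1 learner of the locator and several
# base-classifier registry entries (no tree package ships with the runtime).

# Greedy weighted least-squares regression tree.
# X: n x p matrix; z: targets; w: sample weights; mtry: features tried per
# node (NULL = all). Returns a flat node table (parallel vectors).
fit_rtree <- function(X, z, w, max_depth = 3L, min_leaf = 5L, mtry = NULL) {
  n <- nrow(X); p <- ncol(X)
  feat <- integer(0); thr <- numeric(0); left <- integer(0); right <- integer(0)
  value <- numeric(0); is_leaf <- logical(0)
  new_node <- function() {
    feat[length(feat) + 1L] <<- 0L; thr[length(thr) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L; right[length(right) + 1L] <<- 0L
    value[length(value) + 1L] <<- 0; is_leaf[length(is_leaf) + 1L] <<- TRUE
    length(feat)
  }
  best_split <- function(idx) {
    ws <- w[idx]; zs <- z[idx]
    tot_w <- sum(ws); tot_wz <- sum(ws * zs)
    base <- tot_wz^2 / tot_w
    cols <- if (is.null(mtry) || mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- list(gain = 0, feat = NA_integer_, thr = NA_real_)
    for (j in cols) {
      xv <- X[idx, j]
      o <- order(xv)
      xo <- xv[o]; wo <- ws[o]; zo <- zs[o]
      cw <- cumsum(wo); cwz <- cumsum(wo * zo)
      k <- length(idx)
      valid <- which(xo[-k] < xo[-1L])          # split between distinct values
      valid <- valid[valid >= min_leaf & (k - valid) >= min_leaf]
      if (length(valid) == 0L) next
      gain <- cwz[valid]^2 / cw[valid] +
        (tot_wz - cwz[valid])^2 / (tot_w - cw[valid]) - base
      b <- which.max(gain)
      if (gain[b] > best$gain + 1e-12) {
        best <- list(gain = gain[b], feat = j,
                     thr = (xo[valid[b]] + xo[valid[b] + 1L]) / 2)
      }
    }
    best
  }
  grow <- function(idx, depth) {
    id <- new_node()
    value[id] <<- sum(w[idx] * z[idx]) / sum(w[idx])
    if (depth < max_depth && length(idx) >= 2L * min_leaf) {
      sp <- best_split(idx)
      if (!is.na(sp$feat)) {
        go_left <- X[idx, sp$feat] <= sp$thr
        l <- grow(idx[go_left], depth + 1L)
        r <- grow(idx[!go_left], depth + 1L)
        feat[id] <<- sp$feat; thr[id] <<- sp$thr
        left[id] <<- l; right[id] <<- r; is_leaf[id] <<- FALSE
      }
    }
    id
  }
  root <- grow(seq_len(n), 0L)
  list(feat = feat, thr = thr, left = left, right = right, value = value,
       is_leaf = is_leaf, root = root)
}

# Leaf index for every row of X.
rtree_leaf <- function(tree, X) {
  n <- nrow(X)
  node <- rep(tree$root, n)
  repeat {
    active <- which(!tree$is_leaf[node])
    if (length(active) == 0L) break
    nd <- node[active]
    go_left <- X[cbind(active, tree$feat[nd])] <= tree$thr[nd]
    node[active] <- ifelse(go_left, tree$left[nd], tree$right[nd])
  }
  node
}

predict_rtree <- function(tree, X) tree$value[rtree_leaf(tree, X)]

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gradient-boosted trees for binary classification
#'
#' Binomial-deviance gradient boosting with shallow weighted regression trees
#' and Newton leaf values, supporting per-sample weights and per-tree feature
#' subsampling. This is the level-1 learner of the window-scoring stacking
#' model and a registry base classifier.
#'
#' @param X numeric matrix (rows = samples).
#' @param y 0/1 labels.
#' @param weights per-sample weights (default 1).
#' @param n_trees number of boosting rounds.
#' @param max_depth tree depth.
#' @param learning_rate shrinkage per round.
#' @param min_leaf minimum samples per leaf.
#' @param colsample number of features sampled per tree (NULL = all).
#' @param seed seed for feature subsampling.
#' @return object of class `gbdt`.
#' @export
gbdt_fit <- function(X, y, weights = NULL, n_trees = 200L, max_depth = 6L,
                     learning_rate = 0.05, min_leaf = 5L, colsample = NULL,
                     seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  pbar <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
  f0 <- log(pbar / (1 - pbar))
  Fx <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  withr::with_seed(seed, {
    for (t in seq_len(n_trees)) {
      p <- sigmoid(Fx)
      r <- y - p
      tr <- fit_rtree(X, r, w, max_depth = max_depth, min_leaf = min_leaf,
                      mtry = colsample)
      leaf <- rtree_leaf(tr, X)
      # Newton step per leaf: sum w*(y-p) / sum w*p*(1-p)
      num <- tapply(w * r, leaf, sum)
      den <- tapply(w * p * (1 - p), leaf, sum)
      gamma <- num / pmax(den, 1e-12)
      tr$value[as.integer(names(gamma))] <- as.numeric(gamma)
      # internal node values are unused at prediction time
      Fx <- Fx + learning_rate * tr$value[leaf]
      trees[[t]] <- tr
    }
  })
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = "gbdt")
}

#' @rdname gbdt_fit
#' @param object a fitted `gbdt`.
#' @param newdata matrix to score.
#' @param ... unused.
#' @return probability of class 1 per row.
#' @export
predict.gbdt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Fx <- rep(object$f0, nrow(X))
  for (tr in object$trees) Fx <- Fx + object$learning_rate * predict_rtree(tr, X)
  sigmoid(Fx)
}

#' Random forest (probability averaging) for binary classification
#'
#' Bagged weighted regression trees on the 0/1 response with feature
#' subsampling; the forest probability is the mean leaf value across trees.
#'
#' @inheritParams gbdt_fit
#' @param mtry features tried per node (default `ceiling(sqrt(p))`).
#' @return object of class `rf_prob`.
#' @export
rf_fit <- function(X, y, weights = NULL, n_trees = 50L, max_depth = 8L,
                   min_leaf = 3L, mtry = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(X))))
  trees <- withr::with_seed(seed, lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(n, n, replace = TRUE, prob = w / sum(w))
    fit_rtree(X[idx, , drop = FALSE], y[idx], rep(1, n), max_depth = max_depth,
              min_leaf = min_leaf, mtry = mtry)
  }))
  structure(list(trees = trees), class = "rf_prob")
}

#' @rdname rf_fit
#' @param object a fitted `rf_prob`.
#' @param newdata matrix to score.
#' @param ... unused.
#' @export
predict.rf_prob <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  pm <- vapply(object$trees, function(tr) predict_rtree(tr, X), numeric(nrow(X)))
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1L)
  pmin(pmax(rowMeans(pm), 0), 1)
}
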