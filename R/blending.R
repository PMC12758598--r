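# Blending ensemble with a KAN meta-classifier.
#
# Layer 1: for each signal kind, every registry entry is fit on the 70%
# blend-train split of that signal's 400-column block with 10:1 positive
# class weights. Layer 2: the base classifiers' hard 0/1 labels on the 30%
# holdout, concatenated across signals, are the meta-features; the KAN
# meta-classifier is evaluated by stratified 5-fold CV on them and refit on
# all holdout rows.

#' Stratified blend split of a SignalMatrix
#'
#' @param m a `SignalMatrix`.
#' @param ratio train fraction (default 0.7; the remaining 30% becomes the
#'   blending holdout whose predictions feed the meta-classifier).
#' @param seed integer seed.
#' @return list with `SignalMatrix` elements `train` and `holdout` plus the
#'   index vectors.
#' @export
blend_split <- function(m, ratio = 0.7, seed = 1L) {
  idx <- stratified_split(m$y, ratio, seed)
  list(train = subset_matrix(m, idx$train),
       holdout = subset_matrix(m, idx$holdout),
       train_idx = idx$train, holdout_idx = idx$holdout)
}

#' Fit all registry entries on one signal block
#'
#' Every entry is trained on the signal's feature block with per-sample class
#' weights (default 10 for positives, 1 for negatives). An entry whose fit
#' fails is skipped with a warning; if all fail, an error is raised.
#'
#' @param registry a `BaseClassifierRegistry`.
#' @param train a `SignalMatrix` (blend-train split).
#' @param signal_kind which signal block to use.
#' @param class_weight_ratio positive:negative weight ratio (default 10).
#' @return named list of fitted models (class `FittedBase`), in registry
#'   order, possibly with NULL gaps for skipped entries.
#' @export
train_base <- function(registry, train, signal_kind, class_weight_ratio = 10) {
  Xb <- signal_block(train, signal_kind)
  w <- ifelse(train$y == 1L, class_weight_ratio, 1)
  fitted <- lapply(registry, function(entry) {
    model <- tryCatch(entry$fit(Xb, train$y, w), error = function(e) {
      warning("base classifier '", entry$name, "' failed on ", signal_kind,
              ": ", conditionMessage(e))
      NULL
    })
    if (is.null(model)) NULL else list(entry = entry, model = model)
  })
  names(fitted) <- names(registry)
  if (all(vapply(fitted, is.null, logical(1))))
    stop2("all base classifiers failed on signal ", signal_kind)
  structure(fitted, class = "FittedBase", signal_kind = signal_kind)
}

#' Hard-label meta-features from fitted base classifiers
#'
#' Column j holds the 0/1 prediction (probability >= 0.5) of the j-th fitted
#' registry entry, in registry order.
#'
#' @param fitted a `FittedBase` list from [train_base()].
#' @param Xblock the signal's feature block to score.
#' @return integer matrix, n x number of fitted entries.
#' @export
hard_label_meta_features <- function(fitted, Xblock) {
  keep <- !vapply(fitted, is.null, logical(1))
  if (!any(keep)) stop2("no fitted base classifiers")
  cols <- lapply(fitted[keep], function(f) {
    p <- f$entry$predict_proba(f$model, Xblock)
    as.integer(p >= 0.5)
  })
  mf <- do.call(cbind, cols)
  colnames(mf) <- names(fitted)[keep]
  mf
}

#' Merge per-signal meta-feature matrices
#'
#' Horizontal concatenation in the declared signal order.
#'
#' @param mats named list of meta-feature matrices, one per signal.
#' @param signal_order character vector giving the order.
#' @return merged matrix.
#' @export
merge_signals <- function(mats, signal_order = names(mats)) {
  assert_that(all(signal_order %in% names(mats)), "missing signal matrices")
  n <- unique(vapply(mats[signal_order], nrow, integer(1)))
  if (length(n) != 1L) stop2("meta-feature matrices have mismatched row counts")
  out <- do.call(cbind, lapply(signal_order, function(s) {
    m <- mats[[s]]
    colnames(m) <- paste(s, colnames(m), sep = ".")
    m
  }))
  out
}

#' Cross-validated KAN meta-classifier training
#'
#' Stratified k-fold CV (default 5) over the meta-features: for each fold a
#' fresh KAN is trained on the other folds and evaluated on the held-out
#' fold. The report carries per-fold and mean +/- sd accuracy, AUROC and
#' AUPRC. The returned meta-classifier is refit on all rows.
#'
#' @param meta_features numeric matrix (rows = samples).
#' @param y 0/1 labels.
#' @param cfg a [kan_config()].
#' @param folds number of CV folds.
#' @param seed fold-assignment seed.
#' @param widths optional KAN widths; default `c(p, min(2p, 64), 2)`.
#' @return list with `meta` (trained `KANNetwork`) and `report` (an
#'   `EvalReport` list).
#' @export
train_meta_cv <- function(meta_features, y, cfg = kan_config(), folds = 5L,
                          seed = 1L, widths = NULL) {
  X <- as.matrix(meta_features)
  p <- ncol(X)
  if (is.null(widths)) widths <- c(p, min(2L * p, 64L), 2L)
  fold_id <- stratified_folds(y, folds, seed)
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    net <- init_kan(widths, seed = child_seed(seed, f))
    net <- kan_train(net, X[tr, , drop = FALSE], y[tr], cfg)
    prob <- kan_predict_proba(net, X[!tr, , drop = FALSE])
    m <- classification_metrics(y[!tr], prob)
    c(accuracy = m$accuracy, auroc = m$auroc, auprc = m$auprc)
  })
  fm <- do.call(rbind, per_fold)
  report <- list(folds = folds,
                 per_fold = fm,
                 accuracy = mean(fm[, "accuracy"]), accuracy_sd = sd(fm[, "accuracy"]),
                 auroc = mean(fm[, "auroc"]), auroc_sd = sd(fm[, "auroc"]),
                 auprc = mean(fm[, "auprc"]), auprc_sd = sd(fm[, "auprc"]))
  final <- init_kan(widths, seed = child_seed(seed, 0L))
  final <- kan_train(final, X, y, cfg)
  list(meta = final, report = report)
}

#' Train the full blending model
#'
#' Runs the blend split, layer-1 training per signal, hard-label meta-feature
#' extraction on the holdout, signal merging, and the cross-validated KAN
#' meta-classifier.
#'
#' @param m a `SignalMatrix` with both classes.
#' @param registry a `BaseClassifierRegistry` (default [default_registry()]).
#' @param signal_kinds ordered subset of `m$signal_kinds` (default all).
#' @param ratio blend split ratio (default 0.7).
#' @param class_weight_ratio positive:negative sample-weight ratio (default 10).
#' @param kan_cfg a [kan_config()] for the meta-classifier.
#' @param folds meta-classifier CV folds (default 5).
#' @param seed master seed.
#' @return object of class `BlendingModel` with the CV `report` attached.
#' @export
train_blending <- function(m, registry = default_registry(seed),
                           signal_kinds = m$signal_kinds, ratio = 0.7,
                           class_weight_ratio = 10, kan_cfg = NULL,
                           folds = 5L, seed = 1L) {
  sp <- blend_split(m, ratio, child_seed(seed, 1L))
  fitted <- lapply(signal_kinds, function(s)
    train_base(registry, sp$train, s, class_weight_ratio))
  names(fitted) <- signal_kinds
  mats <- lapply(signal_kinds, function(s)
    hard_label_meta_features(fitted[[s]], signal_block(sp$holdout, s)))
  names(mats) <- signal_kinds
  mf <- merge_signals(mats, signal_kinds)
  if (is.null(kan_cfg))
    kan_cfg <- kan_config(class_weights = c(1, class_weight_ratio),
                          seed = child_seed(seed, 2L))
  meta <- train_meta_cv(mf, sp$holdout$y, kan_cfg, folds, child_seed(seed, 3L))
  structure(list(registry = registry, fitted = fitted, meta = meta$meta,
                 signal_kinds = signal_kinds, split_seed = seed,
                 report = meta$report),
            class = "BlendingModel")
}

#' @export
print.BlendingModel <- function(x, ...) {
  cat("BlendingModel:", length(x$fitted[[1L]]), "base classifiers x",
      length(x$signal_kinds), "signals (",
      paste(x$signal_kinds, collapse = "+"), ")\n")
  cat(sprintf("meta-classifier CV: accuracy %.4f +/- %.4f, AUROC %.4f +/- %.4f\n",
              x$report$accuracy, x$report$accuracy_sd,
              x$report$auroc, x$report$auroc_sd))
  invisible(x)
}

#' Predict enhancer regions with a blending model
#'
#' @param model a `BlendingModel`.
#' @param m a `SignalMatrix` whose signal kinds include all of the model's.
#' @param threshold call threshold on the meta probability (default 0.5).
#' @return data.frame with columns `prob` and `call` (plus region coordinates
#'   when `m` carries a region index).
#' @export
predict_regions <- function(model, m, threshold = 0.5) {
  missing_kind <- setdiff(model$signal_kinds, m$signal_kinds)
  if (length(missing_kind) > 0L)
    stop2("input is missing required signal kind: ",
          paste(missing_kind, collapse = ", "))
  mats <- lapply(model$signal_kinds, function(s)
    hard_label_meta_features(model$fitted[[s]], signal_block(m, s)))
  names(mats) <- model$signal_kinds
  mf <- merge_signals(mats, model$signal_kinds)
  prob <- kan_predict_proba(model$meta, mf)
  out <- data.frame(prob = prob, call = as.integer(prob >= threshold))
  if (!is.null(m$region_index)) {
    out <- cbind(as.data.frame(m$region_index)[c("chrom", "start", "end")], out)
  }
  out
}
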