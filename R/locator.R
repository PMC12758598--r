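# Stage 2: boundary localization. Positive 4000 bp regions are cut into
# 200 bp windows every 50 bp (77 windows), each window is embedded (k-mer
# frequencies by default, external embeddings optionally), scored by a
# stacking model (gradient-boosted level-1 learner, out-of-fold meta-features
# concatenated to the original features, best-of-pool meta-learner), and the
# per-window probability profile is turned into a single boundary call by
# dynamic thresholding.

#' Sliding windows over a region
#'
#' Window offsets are 0, step, 2*step, ... while `offset + window` fits in the
#' region. A 4000 bp region with 200 bp windows and 50 bp step yields 77
#' windows.
#'
#' @param region_length region length in bp.
#' @param window window length in bp (default 200).
#' @param step step size in bp (default 50).
#' @return object of class `WindowSet`: list with `offsets` (start offsets),
#'   `window`, `step`, `region_length` and optional `probs`.
#' @export
make_windows <- function(region_length, window = 200L, step = 50L) {
  assert_that(step >= 1L, "step must be >= 1")
  if (window > region_length)
    stop2("window (", window, ") exceeds region length (", region_length, ")")
  offsets <- seq.int(0L, region_length - window, by = step)
  structure(list(offsets = as.integer(offsets), window = as.integer(window),
                 step = as.integer(step),
                 region_length = as.integer(region_length), probs = NULL),
            class = "WindowSet")
}

#' @export
print.WindowSet <- function(x, ...) {
  cat("WindowSet:", length(x$offsets), "windows of", x$window, "bp, step",
      x$step, "bp over", x$region_length, "bp",
      if (!is.null(x$probs)) "(scored)" else "", "\n")
  invisible(x)
}

KMER_ALPHABET <- c("A", "C", "G", "T")

#' Normalized k-mer frequency embedding
#'
#' Counts all overlapping k-mers of a DNA string and normalizes to sum 1.
#' k-mers containing non-ACGT characters are skipped; if no valid k-mer
#' exists the zero vector is returned. This is the built-in stand-in for an
#' external pretrained sequence embedder.
#'
#' @param seq DNA string (length >= k).
#' @param k k-mer size (default 6, giving a 4096-dimensional vector).
#' @return numeric vector of length `4^k`, named by k-mer.
#' @export
kmer_embed <- function(seq, k = 6L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) stop2("sequence length ", n, " is shorter than k = ", k)
  chars <- strsplit(seq, "")[[1L]]
  code <- match(chars, KMER_ALPHABET) - 1L          # NA for non-ACGT
  # rolling base-4 index of each k-mer
  idx <- integer(n - k + 1L)
  valid <- logical(n - k + 1L)
  pow <- 4L^((k - 1L):0L)
  for (i in seq_len(n - k + 1L)) {
    window <- code[i:(i + k - 1L)]
    if (anyNA(window)) next
    valid[i] <- TRUE
    idx[i] <- sum(window * pow) + 1L
  }
  v <- numeric(4L^k)
  if (any(valid)) {
    tb <- tabulate(idx[valid], nbins = 4L^k)
    v <- tb / sum(tb)
  }
  names(v) <- .all_kmers(k)
  v
}

.all_kmers <- function(k) {
  g <- do.call(expand.grid, c(rep(list(KMER_ALPHABET), k),
                              list(stringsAsFactors = FALSE)))
  # first factor varies slowest in base-4 index order used above
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' k-mer embedder object
#'
#' @param k k-mer size.
#' @return an `Embedder` (kind "kmer") usable with
#'   [predict_window_probs()] and [gen_window_training_set()].
#' @export
kmer_embedder <- function(k = 6L) {
  structure(list(kind = "kmer", k = as.integer(k), dim = 4L^as.integer(k)),
            class = "Embedder")
}

#' Load precomputed window embeddings from delimited text
#'
#' One row per window/sample, constant column count; ragged rows are an
#' error. Used to plug in an external sequence embedder.
#'
#' @param path whitespace/tab-delimited numeric matrix file.
#' @return an `Embedder` (kind "external") carrying the matrix.
#' @export
load_external_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[\t ,]+")
  n_col <- vapply(fields, length, integer(1))
  if (length(unique(n_col)) != 1L)
    stop2("ragged embedding file: rows have ", paste(unique(n_col), collapse = "/"),
          " columns")
  M <- matrix(as.numeric(unlist(fields)), nrow = length(fields), byrow = TRUE)
  structure(list(kind = "external", dim = ncol(M), matrix = M),
            class = "Embedder")
}

# Embed each window of a parent sequence; returns n_windows x dim matrix.
embed_windows <- function(embedder, ws, seq) {
  if (embedder$kind == "kmer") {
    t(vapply(ws$offsets, function(off)
      kmer_embed(substr(seq, off + 1L, off + ws$window), embedder$k),
      numeric(embedder$dim)))
  } else {
    M <- embedder$matrix
    if (nrow(M) != length(ws$offsets))
      stop2("external embeddings have ", nrow(M), " rows but the region has ",
            length(ws$offsets), " windows")
    M
  }
}

#' Out-of-fold meta-features from a level-1 learner
#'
#' Stratified k-fold CV (default 10): sample i's meta-feature is the
#' probability from the fold model whose training fold excluded i. All fold
#' models are returned for inference-time averaging.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param level1 function `(X, y) -> model` whose model answers
#'   `predict(model, X)` with class-1 probabilities; default is the
#'   gradient-boosted tree learner.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `oof` (numeric meta-feature vector) and `fold_models`.
#' @export
oof_meta_features <- function(X, y, level1 = NULL, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(level1)) level1 <- default_level1(seed)
  fold_id <- if (length(unique(y)) < 2L) {
    # degenerate single-class input: plain round-robin folds
    withr::with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
  } else stratified_folds(y, folds, seed)
  oof <- numeric(length(y))
  fold_models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- level1(X[tr, , drop = FALSE], y[tr])
    fold_models[[f]] <- model
    oof[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  list(oof = oof, fold_models = fold_models, fold_id = fold_id)
}

#' Default level-1 learner: gradient-boosted trees
#'
#' 200 rounds of depth-6 trees at learning rate 0.05 with per-tree feature
#' subsampling (up to 64 features), suitable for k-mer features.
#'
#' @param seed seed for feature subsampling.
#' @param n_trees,max_depth,learning_rate boosting hyperparameters.
#' @return a fit function `(X, y) -> gbdt model`.
#' @export
default_level1 <- function(seed = 1L, n_trees = 200L, max_depth = 6L,
                           learning_rate = 0.05) {
  force(seed); force(n_trees); force(max_depth); force(learning_rate)
  function(X, y) gbdt_fit(X, y, n_trees = n_trees, max_depth = max_depth,
                          learning_rate = learning_rate,
                          colsample = min(64L, ncol(X)), seed = seed)
}

#' Default meta-learner candidate pool
#'
#' Gradient-boosted trees, a regularized logistic model (glmnet ridge) and a
#' random forest; each is a named fit function `(X, y) -> model` with a
#' probability `predict` method.
#'
#' @param seed seed for the stochastic candidates.
#' @return named list of fit functions.
#' @export
default_meta_candidates <- function(seed = 1L) {
  list(
    gbdt = function(X, y) gbdt_fit(X, y, n_trees = 100L, max_depth = 3L,
                                   learning_rate = 0.1,
                                   colsample = min(64L, ncol(X)),
                                   seed = child_seed(seed, 21L)),
    logistic = function(X, y) {
      m <- glmnet::glmnet(as.matrix(X), factor(y, levels = c(0L, 1L)),
                          family = "binomial", alpha = 0, lambda = 0.01)
      structure(list(fit = m), class = "glmnet_prob")
    },
    random_forest = function(X, y) rf_fit(X, y, n_trees = 40L, max_depth = 8L,
                                          seed = child_seed(seed, 22L))
  )
}

#' @export
predict.glmnet_prob <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, as.matrix(newdata), type = "response")[, 1L])
}

#' Train the window-scoring stacking model
#'
#' Level 1: out-of-fold probabilities of the gradient-boosted learner
#' (10-fold stratified CV) form one meta-feature column that is concatenated
#' to the original features. Each meta-candidate is fit on the expanded
#' features of an 80% stratified split and scored (accuracy) on the held-out
#' 20%; the best candidate is refit on all expanded rows and stored as the
#' meta-learner.
#'
#' @param X embedded window features (rows = windows/samples).
#' @param y 0/1 labels (enhancer window or not).
#' @param level1 level-1 fit function; default [default_level1()].
#' @param meta_candidates named list of candidate fit functions; default
#'   [default_meta_candidates()].
#' @param folds level-1 CV folds (default 10).
#' @param seed master seed.
#' @return object of class `StackingModel`.
#' @export
train_stacking <- function(X, y, level1 = NULL, meta_candidates = NULL,
                           folds = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2L) stop2("training labels must contain both classes")
  if (is.null(level1)) level1 <- default_level1(child_seed(seed, 1L))
  if (is.null(meta_candidates))
    meta_candidates <- default_meta_candidates(child_seed(seed, 2L))
  oof <- oof_meta_features(X, y, level1, folds, child_seed(seed, 3L))
  Xexp <- cbind(X, meta = oof$oof)
  sp <- stratified_split(y, 0.8, child_seed(seed, 4L))
  scores <- vapply(names(meta_candidates), function(nm) {
    model <- tryCatch(meta_candidates[[nm]](Xexp[sp$train, , drop = FALSE],
                                            y[sp$train]),
                      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    p <- predict(model, Xexp[sp$holdout, , drop = FALSE])
    mean((p >= 0.5) == y[sp$holdout])
  }, numeric(1))
  if (all(is.na(scores))) stop2("all meta-learner candidates failed")
  best <- names(scores)[which.max(scores)]
  meta <- meta_candidates[[best]](Xexp, y)
  structure(list(fold_models = oof$fold_models, folds = folds,
                 meta = meta, meta_name = best, candidate_scores = scores,
                 feature_dim = ncol(X), seed = seed),
            class = "StackingModel")
}

#' @export
print.StackingModel <- function(x, ...) {
  cat("StackingModel:", x$folds, "-fold OOF gradient boosting +", x$meta_name,
      "meta-learner on", x$feature_dim, "+1 features\n")
  invisible(x)
}

# Level-1 meta-feature for unseen data: mean prediction of the fold models.
stacking_meta_feature <- function(model, X) {
  pm <- vapply(model$fold_models, function(m) predict(m, X), numeric(nrow(X)))
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1L)
  rowMeans(pm)
}

#' Probability of each window/sample being an enhancer
#'
#' @param model a `StackingModel`.
#' @param X embedded features (rows = samples).
#' @return class-1 probabilities.
#' @export
predict_stacking <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$feature_dim)
    stop2("feature dim ", ncol(X), " does not match model (", model$feature_dim, ")")
  Xexp <- cbind(X, meta = stacking_meta_feature(model, X))
  predict(model$meta, Xexp)
}

#' Score the sliding windows of a region sequence
#'
#' Embeds each window of `seq`, scores it with the stacking model and
#' attaches the probabilities to the `WindowSet`.
#'
#' @param model a `StackingModel`.
#' @param embedder an `Embedder` ([kmer_embedder()] or
#'   [load_external_embeddings()]).
#' @param windows a `WindowSet` for the region.
#' @param seq the region's DNA sequence (length must equal the window set's
#'   region length; ignored for external embedders).
#' @return the `WindowSet` with `probs` filled in.
#' @export
predict_window_probs <- function(model, embedder, windows, seq) {
  if (embedder$kind == "kmer" && nchar(seq) != windows$region_length)
    stop2("sequence length ", nchar(seq), " does not match region length ",
          windows$region_length)
  E <- embed_windows(embedder, windows, seq)
  windows$probs <- predict_stacking(model, E)
  windows
}

#' Dynamic-threshold boundary call
#'
#' Computes the threshold `t = mean(probs) - mult * sd_pop(probs)` (population
#' standard deviation), retains windows with probability >= t, merges runs of
#' consecutive retained window indices into candidate regions, and returns
#' the candidate with the highest mean probability (leftmost on ties). The
#' call spans from the first retained window's start to the last one's end.
#'
#' @param ws a `WindowSet` with `probs`.
#' @param mult threshold multiplier on the standard deviation (default 0.3).
#' @param parent_start absolute start coordinate of the parent region
#'   (default 0; calls are reported in absolute coordinates).
#' @return object of class `EnhancerCall`: list with `call_start`,
#'   `call_end`, `mean_prob`, `threshold`, `retained_mask`,
#'   `n_candidate_regions` and the window probabilities.
#' @export
dynamic_threshold_call <- function(ws, mult = 0.3, parent_start = 0L) {
  p <- ws$probs
  if (is.null(p) || length(p) == 0L) stop2("window probabilities are missing")
  mu <- mean(p)
  sd_pop <- sqrt(mean((p - mu)^2))
  thr <- mu - mult * sd_pop
  keep <- p >= thr
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- data.frame(first = starts[runs], last = ends[runs])
  cand$mean_prob <- vapply(seq_len(nrow(cand)), function(i)
    mean(p[cand$first[i]:cand$last[i]]), numeric(1))
  best <- which.max(cand$mean_prob)   # which.max takes the leftmost maximum
  first <- cand$first[best]; last <- cand$last[best]
  structure(list(
    call_start = parent_start + ws$offsets[first],
    call_end = parent_start + ws$offsets[last] + ws$window,
    mean_prob = cand$mean_prob[best],
    threshold = thr,
    retained_mask = keep,
    n_candidate_regions = nrow(cand),
    probs = p, window = ws$window, step = ws$step
  ), class = "EnhancerCall")
}

#' @export
print.EnhancerCall <- function(x, ...) {
  cat(sprintf("EnhancerCall: [%d, %d) mean prob %.3f (threshold %.3f, %d candidate run%s)\n",
              x$call_start, x$call_end, x$mean_prob, x$threshold,
              x$n_candidate_regions, if (x$n_candidate_regions == 1L) "" else "s"))
  invisible(x)
}

#' Write enhancer calls as BED6
#'
#' Score column is `round(1000 * mean_prob)`; strand is ".".
#'
#' @param calls list of `EnhancerCall` objects.
#' @param chroms chromosome name per call.
#' @param path output path.
#' @param names_ feature names (default call_1, call_2, ...).
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, chroms, path,
                            names_ = paste0("call_", seq_along(calls))) {
  df <- data.frame(
    chrom = chroms,
    start = vapply(calls, `[[`, numeric(1), "call_start"),
    end = vapply(calls, `[[`, numeric(1), "call_end"),
    name = names_,
    score = round(1000 * vapply(calls, `[[`, numeric(1), "mean_prob")),
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
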