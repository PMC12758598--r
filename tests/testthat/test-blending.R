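# toy deterministic registry entries used throughout
const_entry <- function(name, value) {
  registry_entry(name, fit = function(X, y, w) value,
                 predict_proba = function(m, X) rep(m, nrow(X)))
}
# thresholds on the mean of the feature block
mean_entry <- function(name, cut) {
  registry_entry(name, fit = function(X, y, w) cut,
                 predict_proba = function(m, X) as.numeric(rowMeans(X) > m))
}

toy_matrix <- function(n_pos = 10L, n_neg = 90L, kinds = c("DNase", "H3K27ac"),
                       shift = 2, seed = 1L) {
  n <- n_pos + n_neg
  X <- withr::with_seed(seed, {
    do.call(cbind, lapply(seq_along(kinds), function(k) {
      b <- matrix(rnorm(n * 20), n, 20)
      b[seq_len(n_pos), ] <- b[seq_len(n_pos), ] + shift
      b
    }))
  })
  signal_matrix(X, c(rep(1L, n_pos), rep(0L, n_neg)), kinds, 10L)
}

test_that("blend_split stratifies at 7:3 and is deterministic", {
  m <- toy_matrix(10L, 90L)
  sp <- blend_split(m, 0.7, seed = 3L)
  expect_equal(nrow(sp$train$X), 70L)
  expect_equal(nrow(sp$holdout$X), 30L)
  expect_equal(sum(sp$train$y), 7L)
  expect_equal(sum(sp$holdout$y), 3L)
  expect_identical(blend_split(m, 0.7, seed = 3L)$train_idx, sp$train_idx)
  expect_error(blend_split(m, 1.0, seed = 1L), "ratio")
  single <- signal_matrix(m$X[m$y == 0L, ], rep(0L, 90), m$signal_kinds, 10L)
  expect_error(blend_split(single, 0.7, seed = 1L), "both classes")
})

test_that("train_base fits every registry entry and honors weights", {
  reg <- make_registry(list(const_entry("a", 1), const_entry("b", 0),
                            mean_entry("c", 0.5)))
  m <- toy_matrix()
  fitted <- train_base(reg, m, "DNase")
  expect_length(fitted, 3L)
  expect_named(fitted, c("a", "b", "c"))

  # weight/duplication equivalence for a weight-respecting linear model (glm)
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 2), 60, 2)
    y <- as.integer(X[, 1] + rnorm(60, 0, 0.5) > 0)
  })
  fit_w <- glm.fit(cbind(1, X), y, weights = ifelse(y == 1, 10, 1),
                   family = binomial())
  dup <- c(seq_along(y)[y == 0L], rep(seq_along(y)[y == 1L], 10L))
  fit_d <- glm.fit(cbind(1, X[dup, ]), y[dup], family = binomial())
  expect_equal(coef(fit_w), coef(fit_d), tolerance = 1e-6)

  # failing entries are skipped with a warning; all-fail errors
  bad <- registry_entry("boom", fit = function(X, y, w) stop("nope"),
                        predict_proba = function(m, X) rep(0, nrow(X)))
  expect_warning(f2 <- train_base(make_registry(list(bad, const_entry("a", 1))),
                                  m, "DNase"), "boom")
  expect_null(f2$boom)
  expect_error(suppressWarnings(train_base(make_registry(list(bad)), m, "DNase")),
               "all base classifiers failed")
})

test_that("hard-label meta-features are 0/1 columns in registry order", {
  reg <- make_registry(list(const_entry("all_one", 1), const_entry("all_zero", 0),
                            mean_entry("split", 0.5)))
  m <- toy_matrix()
  fitted <- train_base(reg, m, "DNase")
  mf <- hard_label_meta_features(fitted, signal_block(m, "DNase"))
  expect_equal(dim(mf), c(100L, 3L))
  expect_true(all(mf %in% c(0L, 1L)))
  expect_equal(colnames(mf), c("all_one", "all_zero", "split"))
  expect_true(all(mf[, "all_one"] == 1L))
  expect_true(all(mf[, "all_zero"] == 0L))
  # column order follows the registry even if entries are permuted
  reg2 <- make_registry(list(mean_entry("split", 0.5), const_entry("all_one", 1),
                             const_entry("all_zero", 0)))
  mf2 <- hard_label_meta_features(train_base(reg2, m, "DNase"),
                                  signal_block(m, "DNase"))
  expect_equal(colnames(mf2), c("split", "all_one", "all_zero"))
  expect_equal(mf2[, "split"], mf[, "split"])
})

test_that("merge_signals concatenates in declared order and checks rows", {
  a <- matrix(0L, 5, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  b <- matrix(1L, 5, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  merged <- merge_signals(list(DNase = a, H3K27ac = b), c("DNase", "H3K27ac"))
  expect_equal(ncol(merged), 6L)
  expect_equal(colnames(merged)[1:3], c("DNase.m1", "DNase.m2", "DNase.m3"))
  five <- stats::setNames(rep(list(a), 5),
                          c("DNase", "H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac"))
  expect_equal(ncol(merge_signals(five, names(five))), 15L)
  single <- merge_signals(list(DNase = a), "DNase")
  expect_equal(unname(single), unname(a))
  expect_equal(colnames(single), c("DNase.m1", "DNase.m2", "DNase.m3"))
  expect_error(merge_signals(list(DNase = a, H3K27ac = b[1:3, ]),
                             c("DNase", "H3K27ac")), "row")
})

test_that("train_meta_cv: oracle feature, null features, stratified folds", {
  y <- rep(c(1L, 0L), c(15L, 60L))
  cfg <- kan_config(epochs = 60, learning_rate = 0.02, class_weights = c(1, 1),
                    seed = 1L)
  oracle <- cbind(feat = y)
  res <- train_meta_cv(oracle, y, cfg, folds = 5L, seed = 2L)
  expect_equal(res$report$accuracy, 1.0)
  expect_equal(res$report$auroc, 1.0)

  # fold class ratios within one sample of the global ratio
  folds <- enhancerscan:::stratified_folds(y, 5L, seed = 2L)
  for (f in 1:5) expect_equal(sum(y[folds == f]), 3L)

  null_auroc <- vapply(1:5, function(s) {
    mf <- withr::with_seed(s, matrix(rbinom(75 * 3, 1, 0.5), 75, 3))
    train_meta_cv(mf, y, kan_config(epochs = 15, seed = s), folds = 5L,
                  seed = s)$report$auroc
  }, numeric(1))
  expect_lt(abs(mean(null_auroc) - 0.5), 0.1)
})

test_that("the full blending pipeline separates toy signal data", {
  m <- toy_matrix(20L, 180L, shift = 2)
  model <- train_blending(m, small_registry(1L), seed = 1L,
                          kan_cfg = kan_config(epochs = 30, seed = 1L))
  preds <- predict_regions(model, m)
  expect_true(all(preds$prob >= 0 & preds$prob <= 1))
  expect_gte(mean(preds$call == m$y), 0.95)

  # missing signal errors by name; an extra unused signal changes nothing
  dn_only <- signal_matrix(signal_block(m, "DNase"), m$y, "DNase", 10L)
  expect_error(predict_regions(model, dn_only), "H3K27ac")
  extra <- signal_matrix(cbind(m$X, signal_block(m, "DNase")), m$y,
                         c(m$signal_kinds, "H3K9ac"), 10L)
  expect_equal(predict_regions(model, extra)$prob, preds$prob)
})

test_that("meta-features are invariant to sample order (no order leakage)", {
  m <- toy_matrix()
  reg <- make_registry(list(mean_entry("split", 0.5), const_entry("one", 1)))
  fitted <- train_base(reg, m, "DNase")
  mf <- hard_label_meta_features(fitted, signal_block(m, "DNase"))
  perm <- withr::with_seed(7, sample.int(nrow(m$X)))
  mf_perm <- hard_label_meta_features(fitted, signal_block(m, "DNase")[perm, ])
  expect_equal(mf_perm[order(perm), ], mf)
})

test_that("blending does not fall below the best base classifier (5 seeds)", {
  deltas <- vapply(1:5, function(s) {
    m <- toy_matrix(20L, 180L, shift = 1.5, seed = s)
    model <- train_blending(m, small_registry(s), seed = s,
                            kan_cfg = kan_config(epochs = 30, seed = s))
    sp <- blend_split(m, 0.7, enhancerscan:::child_seed(s, 1L))
    base_acc <- vapply(m$signal_kinds, function(kind) {
      mfh <- hard_label_meta_features(model$fitted[[kind]],
                                      signal_block(sp$holdout, kind))
      apply(mfh, 2L, function(col) mean(col == sp$holdout$y))
    }, numeric(length(small_registry(s))))
    model$report$accuracy - max(base_acc)
  }, numeric(1))
  expect_true(all(deltas >= -0.02))
})
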