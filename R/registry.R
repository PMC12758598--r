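# Base-classifier registry for the blending ensemble. Each entry is a named
# learner with fit(X, y, w) -> model and predict_proba(model, X) -> p(class 1).
# The registry order is fixed and defines the meta-feature column order.

.weighted_colstats <- function(X, w) {
  sw <- sum(w)
  mu <- colSums(X * w) / sw
  v <- colSums(sweep(X, 2L, mu)^2 * w) / sw
  list(mu = mu, var = pmax(v, 1e-9))
}

# Gaussian naive Bayes with per-sample weights.
nb_fit <- function(X, y, w) {
  X <- as.matrix(X)
  s0 <- .weighted_colstats(X[y == 0L, , drop = FALSE], w[y == 0L])
  s1 <- .weighted_colstats(X[y == 1L, , drop = FALSE], w[y == 1L])
  prior1 <- sum(w[y == 1L]) / sum(w)
  list(s0 = s0, s1 = s1, logit_prior = log(prior1 / (1 - prior1)))
}

nb_predict <- function(model, X) {
  X <- as.matrix(X)
  ll <- function(s) {
    -0.5 * rowSums(sweep(sweep(X, 2L, s$mu)^2, 2L, s$var, "/")) -
      0.5 * sum(log(2 * pi * s$var))
  }
  sigmoid(ll(model$s1) - ll(model$s0) + model$logit_prior)
}

# Diagonal LDA: weighted class means, pooled per-feature variance.
dlda_fit <- function(X, y, w) {
  X <- as.matrix(X)
  s0 <- .weighted_colstats(X[y == 0L, , drop = FALSE], w[y == 0L])
  s1 <- .weighted_colstats(X[y == 1L, , drop = FALSE], w[y == 1L])
  sw <- sum(w)
  pooled <- pmax((sum(w[y == 0L]) * s0$var + sum(w[y == 1L]) * s1$var) / sw, 1e-9)
  prior1 <- sum(w[y == 1L]) / sum(w)
  list(mu0 = s0$mu, mu1 = s1$mu, var = pooled,
       logit_prior = log(prior1 / (1 - prior1)))
}

dlda_predict <- function(model, X) {
  X <- as.matrix(X)
  d1 <- rowSums(sweep(sweep(X, 2L, model$mu1)^2, 2L, model$var, "/"))
  d0 <- rowSums(sweep(sweep(X, 2L, model$mu0)^2, 2L, model$var, "/"))
  sigmoid(0.5 * (d0 - d1) + model$logit_prior)
}

# k-nearest neighbours with weight-proportional voting.
knn_fit <- function(X, y, w, k = 5L) {
  list(X = as.matrix(X), y = as.integer(y), w = as.numeric(w), k = as.integer(k))
}

knn_predict <- function(model, X) {
  X <- as.matrix(X)
  tr <- model$X
  k <- min(model$k, nrow(tr))
  # squared Euclidean distances, vectorized
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  apply(d2, 1L, function(di) {
    nb <- order(di)[seq_len(k)]
    sum(model$w[nb] * (model$y[nb] == 1L)) / sum(model$w[nb])
  })
}

glmnet_entry_fit <- function(alpha, lambda) {
  function(X, y, w) {
    glmnet::glmnet(as.matrix(X), factor(y, levels = c(0L, 1L)),
                   family = "binomial", weights = w, alpha = alpha,
                   lambda = lambda, standardize = TRUE)
  }
}

glmnet_entry_predict <- function(model, X) {
  as.numeric(predict(model, as.matrix(X), type = "response")[, 1L])
}

#' Base-classifier registry entry
#'
#' @param name unique entry name (meta-feature column label).
#' @param fit function `(X, y, w) -> model` honouring per-sample weights.
#' @param predict_proba function `(model, X) -> p(class 1)`.
#' @return list of class `RegistryEntry`.
#' @export
registry_entry <- function(name, fit, predict_proba) {
  assert_that(nzchar(name), "entry name must be non-empty")
  structure(list(name = name, fit = fit, predict_proba = predict_proba),
            class = "RegistryEntry")
}

#' Default base-classifier registry
#'
#' Eight diverse tabular learners: two regularized logistic models (glmnet
#' ridge and lasso), Gaussian naive Bayes, diagonal LDA, weighted kNN, two
#' gradient-boosted tree configurations and a random forest. All honour
#' per-sample weights (kNN through weighted voting). The ordered entry list
#' defines the meta-feature column order; users can pass their own list of
#' [registry_entry()] objects anywhere a registry is accepted.
#'
#' @param seed seed forwarded to the stochastic learners.
#' @return list of class `BaseClassifierRegistry`.
#' @export
default_registry <- function(seed = 1L) {
  entries <- list(
    registry_entry("logistic_l2", glmnet_entry_fit(0, 0.01), glmnet_entry_predict),
    registry_entry("logistic_l1", glmnet_entry_fit(1, 0.005), glmnet_entry_predict),
    registry_entry("naive_bayes", nb_fit, nb_predict),
    registry_entry("dlda", dlda_fit, dlda_predict),
    registry_entry("knn5", function(X, y, w) knn_fit(X, y, w, 5L), knn_predict),
    registry_entry("gbdt_stump",
                   function(X, y, w) gbdt_fit(X, y, w, n_trees = 100L,
                                              max_depth = 1L, learning_rate = 0.1,
                                              colsample = min(64L, ncol(X)),
                                              seed = child_seed(seed, 11L)),
                   function(m, X) predict(m, X)),
    registry_entry("gbdt_shallow",
                   function(X, y, w) gbdt_fit(X, y, w, n_trees = 60L,
                                              max_depth = 3L, learning_rate = 0.1,
                                              colsample = min(64L, ncol(X)),
                                              seed = child_seed(seed, 12L)),
                   function(m, X) predict(m, X)),
    registry_entry("random_forest",
                   function(X, y, w) rf_fit(X, y, w, n_trees = 40L, max_depth = 6L,
                                            seed = child_seed(seed, 13L)),
                   function(m, X) predict(m, X))
  )
  make_registry(entries)
}

#' Assemble a registry from entries
#'
#' @param entries list of [registry_entry()] objects with unique names.
#' @return list of class `BaseClassifierRegistry`.
#' @export
make_registry <- function(entries) {
  assert_that(length(entries) >= 1L, "registry needs at least one entry")
  nm <- vapply(entries, `[[`, character(1), "name")
  assert_that(!anyDuplicated(nm), "registry entry names must be unique")
  structure(entries, class = "BaseClassifierRegistry", names = nm)
}

#' A small fast registry for tests and scaled-down simulations
#'
#' @inheritParams default_registry
#' @export
small_registry <- function(seed = 1L) {
  make_registry(list(
    registry_entry("logistic_l2", glmnet_entry_fit(0, 0.01), glmnet_entry_predict),
    registry_entry("naive_bayes", nb_fit, nb_predict),
    registry_entry("gbdt_stump",
                   function(X, y, w) gbdt_fit(X, y, w, n_trees = 40L,
                                              max_depth = 1L, learning_rate = 0.15,
                                              colsample = min(32L, ncol(X)),
                                              seed = child_seed(seed, 11L)),
                   function(m, X) predict(m, X))
  ))
}
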