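#' Kolmogorov-Arnold network (KAN) binary classifier
#'
#' A KAN places a learnable univariate function on every edge of the network:
#' `phi(x) = w_res * silu(x) + sum_j c_j * B_j(x)`, where `B_j` are degree-k
#' B-spline basis functions on a fixed uniform grid over `input_range` and
#' `silu(x) = x * sigmoid(x)` is a fixed smooth residual. A node outputs its
#' bias plus the sum of incoming edge values. The final layer has two output
#' logits; training minimizes class-weighted softmax cross-entropy with
#' Adam-style updates. Inputs outside `input_range` are clamped for basis
#' evaluation (the residual path still sees the raw value).
#'
#' @param widths integer vector of layer widths; first entry is the input
#'   dimension, last must be 2 (binary logits).
#' @param grid_size number of grid intervals G (>= 1); each edge carries
#'   `G + spline_order` spline coefficients.
#' @param spline_order B-spline degree k (>= 1); default cubic.
#' @param input_range numeric length-2 grid support; the default (-1, 3)
#'   comfortably covers 0/1 meta-features.
#' @param seed integer seed for parameter initialization.
#' @return object of class `KANNetwork`.
#' @export
init_kan <- function(widths, grid_size = 5L, spline_order = 3L,
                     input_range = c(-1, 3), seed = 1L) {
  assert_that(length(widths) >= 2L && all(widths >= 1L),
              "widths must list >= 2 positive layer sizes")
  assert_that(widths[length(widths)] == 2L, "final width must be 2 (binary logits)")
  assert_that(grid_size >= 1L, "grid_size must be >= 1")
  assert_that(spline_order >= 1L, "spline_order must be >= 1")
  assert_that(input_range[2L] > input_range[1L], "input_range must be increasing")
  m <- grid_size + spline_order
  layers <- withr::with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      d_in <- widths[l]; d_out <- widths[l + 1L]
      list(
        C = matrix(rnorm(d_out * d_in * m, sd = 0.1 / sqrt(d_in)), d_out, d_in * m),
        Wres = matrix(1, d_out, d_in),
        b = numeric(d_out)
      )
    })
  })
  structure(list(widths = as.integer(widths), grid_size = as.integer(grid_size),
                 spline_order = as.integer(spline_order),
                 input_range = as.numeric(input_range), layers = layers,
                 seed = as.integer(seed)),
            class = "KANNetwork")
}

silu <- function(x) x / (1 + exp(-x))
silu_deriv <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# Arrange basis values of an n x d matrix into n x (d*m) block layout
# (input i occupies columns (i-1)*m + 1 .. i*m).
.kan_basis_blocks <- function(X, net, deriv = FALSE) {
  n <- nrow(X); d <- ncol(X)
  lo <- net$input_range[1L]; hi <- net$input_range[2L]
  f <- if (deriv) bspline_basis_deriv else bspline_basis
  Ball <- f(as.vector(X), lo, hi, net$grid_size, net$spline_order)
  m <- ncol(Ball)
  out <- matrix(0, n, d * m)
  for (i in seq_len(d))
    out[, ((i - 1L) * m + 1L):(i * m)] <- Ball[((i - 1L) * n + 1L):(i * n), , drop = FALSE]
  out
}

# Forward pass keeping per-layer caches for backprop.
.kan_forward_cached <- function(net, X) {
  caches <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    B <- .kan_basis_blocks(A, net)
    S <- silu(A)
    Z <- S %*% t(ly$Wres) + B %*% t(ly$C) +
      matrix(ly$b, nrow(A), length(ly$b), byrow = TRUE)
    caches[[l]] <- list(A = A, B = B, S = S)
    A <- Z
  }
  list(logits = A, caches = caches)
}

#' Forward pass: logits
#'
#' @param net a `KANNetwork`.
#' @param x numeric vector (one sample) or matrix (samples in rows) with
#'   `widths[1]` features.
#' @return n x 2 matrix of logits.
#' @export
kan_forward <- function(net, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != net$widths[1L])
    stop2("input has ", ncol(X), " features; network expects ", net$widths[1L])
  .kan_forward_cached(net, X)$logits
}

#' Class-1 probabilities
#'
#' Softmax over the two logits; returns the probability of label 1.
#'
#' @inheritParams kan_forward
#' @return numeric vector of probabilities in [0, 1].
#' @export
kan_predict_proba <- function(net, x) {
  z <- kan_forward(net, x)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  (e[, 2L] / rowSums(e))
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Loss and analytic gradients of the weighted cross-entropy
#'
#' Exposed so the gradients can be checked against finite differences.
#'
#' @param net a `KANNetwork`.
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param class_weights numeric length-2 vector `c(w0, w1)` of per-class loss
#'   weights.
#' @return list with `loss` (scalar) and `grads` (per layer: `C`, `Wres`, `b`
#'   arrays matching the parameter shapes).
#' @export
kan_gradients <- function(net, X, y, class_weights = c(1, 1)) {
  X <- as.matrix(X)
  n <- nrow(X)
  fw <- .kan_forward_cached(net, X)
  P <- .softmax(fw$logits)
  w <- class_weights[y + 1L]
  wsum <- sum(w)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- sum(w * (-log(pmax(P[pick], 1e-12)))) / wsum
  Y <- matrix(0, n, 2L); Y[pick] <- 1
  dZ <- (P - Y) * (w / wsum)
  grads <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cc <- fw$caches[[l]]
    grads[[l]] <- list(
      C = t(dZ) %*% cc$B,
      Wres = t(dZ) %*% cc$S,
      b = colSums(dZ)
    )
    if (l > 1L) {
      m <- net$grid_size + net$spline_order
      d_in <- net$widths[l]
      Bd <- .kan_basis_blocks(cc$A, net, deriv = TRUE)
      D <- dZ %*% ly$C          # n x (d_in * m)
      dA <- (dZ %*% ly$Wres) * silu_deriv(cc$A)
      tmp <- D * Bd
      for (i in seq_len(d_in))
        dA[, i] <- dA[, i] + rowSums(tmp[, ((i - 1L) * m + 1L):(i * m), drop = FALSE])
      dZ <- dA
    }
  }
  list(loss = loss, grads = grads)
}

#' Flatten / restore KAN parameters
#'
#' Utility pair used for optimization bookkeeping and gradient checking.
#'
#' @param net a `KANNetwork`.
#' @return `kan_get_params`: numeric vector of all parameters.
#' @export
kan_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly) c(ly$C, ly$Wres, ly$b)))
}

#' @rdname kan_get_params
#' @param theta numeric vector as returned by [kan_get_params()].
#' @export
kan_set_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    for (nm in c("C", "Wres", "b")) {
      k <- length(ly[[nm]])
      v <- theta[(pos + 1L):(pos + k)]
      if (is.matrix(ly[[nm]])) dim(v) <- dim(ly[[nm]])
      net$layers[[l]][[nm]] <- v
      pos <- pos + k
    }
  }
  net
}

#' KAN training configuration
#'
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size (batches at the tail may be smaller).
#' @param learning_rate Adam step size.
#' @param class_weights length-2 vector `c(w0, w1)`; the conventional setting
#'   for 1:10 imbalanced enhancer data is `c(1, 10)`.
#' @param seed seed controlling shuffling (and nothing else).
#' @return list of class `KANTrainConfig`.
#' @export
kan_config <- function(epochs = 100L, batch_size = 256L, learning_rate = 1e-3,
                       class_weights = c(1, 10), seed = 1L) {
  assert_that(epochs >= 1L, "epochs must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(all(class_weights > 0), "class weights must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "KANTrainConfig")
}

#' Train a KAN classifier
#'
#' Minimizes class-weighted softmax cross-entropy by mini-batch Adam
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). The loss trace records the
#' full-data loss after every epoch. Deterministic given `cfg$seed`.
#'
#' @param net an initialized `KANNetwork`.
#' @param X feature matrix (rows = samples).
#' @param y 0/1 labels.
#' @param cfg a [kan_config()].
#' @return the trained `KANNetwork` with attribute `loss_trace`.
#' @export
kan_train <- function(net, X, y, cfg = kan_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  assert_that(all(y %in% c(0L, 1L)), "labels must be 0/1")
  assert_that(ncol(X) == net$widths[1L], "feature count must match network input width")
  theta <- kan_get_params(net)
  m_t <- numeric(length(theta)); v_t <- numeric(length(theta))
  step <- 0L
  trace <- numeric(cfg$epochs)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(X))
      for (start in seq(1L, nrow(X), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, nrow(X))]
        g <- kan_gradients(net, X[idx, , drop = FALSE], y[idx], cfg$class_weights)
        if (!is.finite(g$loss))
          stop2("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
        gv <- unlist(lapply(g$grads, function(ly) c(ly$C, ly$Wres, ly$b)))
        step <- step + 1L
        m_t <- b1 * m_t + (1 - b1) * gv
        v_t <- b2 * v_t + (1 - b2) * gv^2
        mhat <- m_t / (1 - b1^step)
        vhat <- v_t / (1 - b2^step)
        theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        net <- kan_set_params(net, theta)
      }
      trace[ep] <- kan_gradients(net, X, y, cfg$class_weights)$loss
    }
  })
  attr(net, "loss_trace") <- trace
  net
}

#' Save / load a KAN as self-describing JSON
#'
#' @param net a `KANNetwork`.
#' @param path output path.
#' @export
save_kan <- function(net, path) {
  obj <- list(widths = net$widths, grid_size = net$grid_size,
              spline_order = net$spline_order, input_range = net$input_range,
              seed = net$seed, params = kan_get_params(net))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kan
#' @export
load_kan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- init_kan(obj$widths, obj$grid_size, obj$spline_order, obj$input_range,
                  obj$seed)
  kan_set_params(net, obj$params)
}
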