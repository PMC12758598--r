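# Uniform B-spline basis on [lo, hi] with G intervals and degree k.
# Knots are the uniform extension lo + h*(-k .. G+k), h = (hi-lo)/G, giving
# G + k basis functions of degree k that form a partition of unity on [lo, hi].

bspline_knots <- function(lo, hi, G, k) {
  h <- (hi - lo) / G
  lo + h * seq.int(-k, G + k)
}

# Evaluate all degree-k basis functions at x (clamped to [lo, hi]).
# Returns length(x) x (G + k) matrix. Cox-de Boor recursion, vectorized in x.
bspline_basis <- function(x, lo, hi, G, k) {
  t <- bspline_knots(lo, hi, G, k)
  x <- pmin(pmax(x, lo), hi)
  n_knots <- length(t)
  # degree 0: indicator of [t_j, t_{j+1}); x == hi goes to the last interval
  B <- matrix(0, length(x), n_knots - 1L)
  for (j in seq_len(n_knots - 1L)) {
    B[, j] <- as.numeric(x >= t[j] & x < t[j + 1L])
  }
  at_hi <- x >= hi
  if (any(at_hi)) {
    B[at_hi, ] <- 0
    B[at_hi, G + k] <- 1  # last interval [t_{G+k}, t_{G+k+1}) contains hi
  }
  if (k == 0L) return(B[, seq_len(G + k), drop = FALSE])
  for (d in seq_len(k)) {
    nb <- n_knots - 1L - d
    Bnew <- matrix(0, length(x), nb)
    for (j in seq_len(nb)) {
      den1 <- t[j + d] - t[j]
      den2 <- t[j + d + 1L] - t[j + 1L]
      a <- if (den1 > 0) (x - t[j]) / den1 * B[, j] else 0
      b <- if (den2 > 0) (t[j + d + 1L] - x) / den2 * B[, j + 1L] else 0
      Bnew[, j] <- a + b
    }
    B <- Bnew
  }
  B
}

# Derivative of each degree-k basis function at x. Points outside [lo, hi]
# get derivative 0 (clamped evaluation is constant there).
bspline_basis_deriv <- function(x, lo, hi, G, k) {
  assert_that(k >= 1, "derivative needs degree >= 1")
  t <- bspline_knots(lo, hi, G, k)
  inside <- x >= lo & x <= hi
  # degree k-1 basis on the degree-k knot vector (G + k + 1 functions)
  n_knots <- length(t)
  B <- matrix(0, length(x), n_knots - 1L)
  xc <- pmin(pmax(x, lo), hi)
  for (j in seq_len(n_knots - 1L)) B[, j] <- as.numeric(xc >= t[j] & xc < t[j + 1L])
  at_hi <- xc >= hi
  if (any(at_hi)) { B[at_hi, ] <- 0; B[at_hi, G + k] <- 1 }
  if (k - 1L >= 1L) {
    for (d in seq_len(k - 1L)) {
      nb <- n_knots - 1L - d
      Bnew <- matrix(0, length(x), nb)
      for (j in seq_len(nb)) {
        den1 <- t[j + d] - t[j]
        den2 <- t[j + d + 1L] - t[j + 1L]
        a <- if (den1 > 0) (xc - t[j]) / den1 * B[, j] else 0
        b <- if (den2 > 0) (t[j + d + 1L] - xc) / den2 * B[, j + 1L] else 0
        Bnew[, j] <- a + b
      }
      B <- Bnew
    }
  }
  m <- G + k
  D <- matrix(0, length(x), m)
  for (j in seq_len(m)) {
    den1 <- t[j + k] - t[j]
    den2 <- t[j + k + 1L] - t[j + 1L]
    a <- if (den1 > 0) B[, j] / den1 else 0
    b <- if (den2 > 0) B[, j + 1L] / den2 else 0
    D[, j] <- k * (a - b)
  }
  D[!inside, ] <- 0
  D
}
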