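# Independent oracles and toy-fixture builders shared across tests. Every
# oracle is a deliberately naive reimplementation (per-base masks, recursive
# definitions, O(n^2) pair counting, exhaustive enumeration) kept separate
# from the package's own algorithms.

# --- per-base interval oracles -----------------------------------------------

# boolean coverage mask of a PeakSet on one chromosome of length L (1-based)
coverage_mask <- function(ps, chrom, L) {
  mask <- logical(L)
  d <- as.data.frame(ps)
  d <- d[d$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    if (d$start[i] < L && d$end[i] > 0)
      mask[(max(d$start[i], 0) + 1):min(d$end[i], L)] <- TRUE
  }
  mask
}

# intervals (0-based half-open) of the TRUE runs of a mask
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

random_peaks <- function(n, L, max_len = 100L, source_kind = "STARR") {
  s <- sample.int(L - 2L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  peak_set(rep("chrT", n), s, pmin(s + len, L), source_kind)
}

# --- recursive B-spline oracle ----------------------------------------------

# textbook Cox-de Boor recursion, one basis function at one point
bspline_oracle <- function(x, j, k, knots) {
  if (k == 0) {
    # right-closed at the final interval end to mirror clamped evaluation
    if (j == length(knots) - 1) return(as.numeric(x >= knots[j] & x <= knots[j + 1]))
    return(as.numeric(x >= knots[j] & x < knots[j + 1]))
  }
  d1 <- knots[j + k] - knots[j]
  d2 <- knots[j + k + 1] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * bspline_oracle(x, j, k - 1, knots) else 0
  b <- if (d2 > 0) (knots[j + k + 1] - x) / d2 * bspline_oracle(x, j + 1, k - 1, knots) else 0
  a + b
}

# --- metric oracles ----------------------------------------------------------

# O(n^2) pairwise AUROC: P(score_pos > score_neg) + 0.5 P(tie)
auroc_oracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# --- dynamic-threshold oracle -------------------------------------------------

# exhaustive: threshold, list every maximal retained run, argmax of mean
dynamic_call_oracle <- function(probs, mult = 0.3, window = 200L, step = 50L) {
  mu <- mean(probs)
  thr <- mu - mult * sqrt(mean((probs - mu)^2))
  keep <- probs >= thr
  runs <- list()
  i <- 1L
  while (i <= length(probs)) {
    if (keep[i]) {
      j <- i
      while (j < length(probs) && keep[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  means <- vapply(runs, function(r) mean(probs[r[1]:r[2]]), numeric(1))
  best <- runs[[which.max(means)]]
  offsets <- (seq_along(probs) - 1L) * step
  list(call_start = offsets[best[1]], call_end = offsets[best[2]] + window,
       mean_prob = max(means), threshold = thr, n_runs = length(runs))
}

# naive k-mer counting oracle
kmer_count_oracle <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  tab <- table(kmers)
  tab / sum(tab)
}

# --- small file fixtures ------------------------------------------------------

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}
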