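#' Construct a signal track
#'
#' A SignalTrack stores interval signal values (bedGraph semantics): per-base
#' value `value` over `[start, end)`, 0-based half-open. Intervals must not
#' overlap within a chromosome; uncovered bases have value 0.
#'
#' @param chrom,start,end interval coordinates.
#' @param value numeric signal values (finite).
#' @param signal_kind assay name; see [peak_set()].
#' @return data.frame of class `SignalTrack`.
#' @export
signal_track <- function(chrom, start, end, value, signal_kind = "DNase") {
  signal_kind <- match.arg(signal_kind, SOURCE_KINDS)
  assert_that(all(end > start), "track interval end must exceed start")
  assert_that(all(is.finite(value)), "track values must be finite")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_ch <- split(df, df$chrom)
  for (d in by_ch) {
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop2("overlapping track intervals on ", d$chrom[1L])
  }
  structure(df, class = c("SignalTrack", "data.frame"), signal_kind = signal_kind)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (chrom, start, end, value); `track`/`#` lines
#'   are skipped.
#' @param signal_kind assay name.
#' @return a `SignalTrack`.
#' @export
read_bedgraph <- function(path, signal_kind = "DNase") {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "[\t ]+")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 4L))
    stop2("malformed bedGraph line ", line_no[which(n_col < 4L)[1L]], " in ", path)
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(val))
    stop2("non-numeric value on line ", line_no[which(is.na(val))[1L]], " in ", path)
  signal_track(vapply(fields, `[[`, character(1), 1L),
               as.integer(vapply(fields, `[[`, character(1), 2L)),
               as.integer(vapply(fields, `[[`, character(1), 3L)),
               val, signal_kind)
}

#' Bin a signal over a region
#'
#' Averages per-base signal in consecutive fixed-width bins across a region.
#' Bases not covered by the track contribute 0.
#'
#' @param track a `SignalTrack`.
#' @param region one-row `GenomicRegionList` (or list with chrom/start/end).
#' @param bin_size bin width in bp; region length must be divisible by it.
#' @return numeric vector of length `(end - start) / bin_size` of bin means.
#' @export
bin_signal <- function(track, region, bin_size = 10L) {
  s <- as.integer(region$start[1L]); e <- as.integer(region$end[1L])
  ch <- as.character(region$chrom[1L])
  len <- e - s
  if (len %% bin_size != 0L)
    stop2("region length ", len, " not divisible by bin size ", bin_size)
  base <- numeric(len)
  tr <- track[track$chrom == ch & track$end > s & track$start < e, , drop = FALSE]
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      a <- max(tr$start[i], s) - s + 1L
      b <- min(tr$end[i], e) - s
      base[a:b] <- tr$value[i]
    }
  }
  n_bins <- len %/% bin_size
  colMeans(matrix(base, nrow = bin_size, ncol = n_bins))
}

#' Build a binned signal feature matrix
#'
#' For each region and each requested signal kind, bins the matching track
#' into a fixed-length block (region length / bin size values) and
#' concatenates the blocks column-wise in the given signal order.
#'
#' @param regions `GenomicRegionList` with labels.
#' @param tracks named list mapping signal kind to `SignalTrack`.
#' @param signal_kinds ordered character vector of kinds to use.
#' @param bin_size bin width in bp (default 10, giving 400 columns per signal
#'   for 4000 bp regions).
#' @return a `SignalMatrix`: list with matrix `X`, labels `y` (0/1),
#'   `signal_kinds`, `bin_size` and `region_index`.
#' @export
build_matrix <- function(regions, tracks, signal_kinds = names(tracks),
                         bin_size = 10L) {
  missing_kind <- setdiff(signal_kinds, names(tracks))
  if (length(missing_kind) > 0L)
    stop2("no track supplied for signal kind: ", paste(missing_kind, collapse = ", "))
  n <- nrow(regions)
  len <- regions$end[1L] - regions$start[1L]
  n_bins <- len %/% bin_size
  blocks <- lapply(signal_kinds, function(kind) {
    t(vapply(seq_len(n), function(i)
      bin_signal(tracks[[kind]], regions[i, , drop = FALSE], bin_size),
      numeric(n_bins)))
  })
  X <- do.call(cbind, blocks)
  y <- as.integer(regions$label == "positive")
  signal_matrix(X, y, signal_kinds, bin_size, regions)
}

#' Construct a SignalMatrix container
#'
#' @param X numeric matrix, n_samples x (bins_per_signal * n_signals).
#' @param y binary labels (0/1).
#' @param signal_kinds ordered character vector; column count must be
#'   divisible by `length(signal_kinds)`.
#' @param bin_size bin width the features were computed at.
#' @param region_index optional `GenomicRegionList` aligned to rows.
#' @return list of class `SignalMatrix`.
#' @export
signal_matrix <- function(X, y, signal_kinds, bin_size = 10L,
                          region_index = NULL) {
  X <- as.matrix(X)
  assert_that(all(y %in% c(0L, 1L)), "labels must be 0/1")
  assert_that(nrow(X) == length(y), "X rows must match labels")
  assert_that(ncol(X) %% length(signal_kinds) == 0L,
              "column count must be divisible by the number of signals")
  if (!is.null(region_index))
    assert_that(nrow(region_index) == nrow(X), "region_index must align with rows")
  structure(list(X = X, y = as.integer(y), signal_kinds = signal_kinds,
                 bin_size = as.integer(bin_size), region_index = region_index),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat("SignalMatrix:", nrow(x$X), "samples x", ncol(x$X), "features (",
      paste(x$signal_kinds, collapse = "+"), ");",
      sum(x$y == 1L), "positive /", sum(x$y == 0L), "negative\n")
  invisible(x)
}

#' Extract one signal's column block from a SignalMatrix
#'
#' @param m a `SignalMatrix`.
#' @param kind one of `m$signal_kinds`.
#' @return numeric matrix of that signal's columns.
#' @export
signal_block <- function(m, kind) {
  j <- match(kind, m$signal_kinds)
  if (is.na(j)) stop2("signal kind not in matrix: ", kind)
  w <- ncol(m$X) %/% length(m$signal_kinds)
  m$X[, ((j - 1L) * w + 1L):(j * w), drop = FALSE]
}

# Row-subset a SignalMatrix
subset_matrix <- function(m, idx) {
  signal_matrix(m$X[idx, , drop = FALSE], m$y[idx], m$signal_kinds, m$bin_size,
                if (!is.null(m$region_index)) m$region_index[idx, , drop = FALSE])
}

#' Add elementwise Gaussian noise to a SignalMatrix
#'
#' Emulates measurement noise on the binned signals: `X' = X + N(0, sigma^2)`
#' elementwise. Labels are unchanged; deterministic given `seed`.
#'
#' @param m a `SignalMatrix`.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return a new `SignalMatrix`.
#' @export
add_gaussian_noise <- function(m, sigma, seed) {
  if (sigma < 0) stop2("sigma must be >= 0")
  if (sigma == 0) return(m)
  noise <- withr::with_seed(seed,
    matrix(rnorm(length(m$X), 0, sigma), nrow(m$X), ncol(m$X)))
  signal_matrix(m$X + noise, m$y, m$signal_kinds, m$bin_size, m$region_index)
}

#' Write / read a SignalMatrix as delimited text plus a JSON sidecar
#'
#' The matrix goes to `<path>` as TSV (no header); metadata (signal order,
#' bin size, labels, region index) goes to `<path>.json`.
#'
#' @param m a `SignalMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(m, path) {
  write.table(m$X, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(signal_kinds = m$signal_kinds, bin_size = m$bin_size, y = m$y)
  if (!is.null(m$region_index))
    meta$region_index <- as.data.frame(m$region_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  ri <- if (!is.null(meta$region_index))
    genomic_regions(meta$region_index$chrom, meta$region_index$start,
                    meta$region_index$end, meta$region_index$label)
  signal_matrix(X, meta$y, meta$signal_kinds, meta$bin_size, ri)
}
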