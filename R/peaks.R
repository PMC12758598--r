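SOURCE_KINDS <- c("STARR", "DNase", "H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac")

#' Construct a set of genomic peaks
#'
#' A PeakSet is an ordered collection of genomic intervals in 0-based
#' half-open (BED) coordinates, sorted by (chrom, start).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param source_kind one of `"STARR"`, `"DNase"`, `"H3K27ac"`, `"H3K4me3"`,
#'   `"H3K4me1"`, `"H3K9ac"`.
#' @return an object of class `PeakSet`: a data.frame with columns chrom,
#'   start, end and attribute `source_kind`.
#' @export
peak_set <- function(chrom, start, end, source_kind = "STARR") {
  source_kind <- match.arg(source_kind, SOURCE_KINDS)
  assert_that(length(chrom) == length(start) && length(start) == length(end),
              "chrom, start, end must have equal length")
  start <- as.integer(start); end <- as.integer(end)
  bad <- which(end <= start)
  if (length(bad) > 0L)
    stop2("invalid peak (end <= start) at row ", bad[1L])
  assert_that(all(nzchar(chrom)), "chrom names must be non-empty")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"), source_kind = source_kind)
}

#' Read peaks from a BED file
#'
#' Parses a BED3+ file (tab- or space-delimited, optional `track`/`#` lines
#' skipped) into a sorted [peak_set()]. Coordinates are validated; a
#' malformed or invalid line raises an error naming the offending line.
#'
#' @param path path to a BED file with at least 3 columns.
#' @param source_kind the assay the peaks come from; see [peak_set()].
#' @return a `PeakSet`.
#' @export
read_peaks <- function(path, source_kind = "STARR") {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop2("no records in BED file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L))
    stop2("malformed BED line ", line_no[which(n_col < 3L)[1L]],
          " in ", path, ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stop2("malformed BED line ", line_no[which(is.na(start) | is.na(end))[1L]],
          " in ", path, ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad) > 0L)
    stop2("invalid interval (end <= start) on line ", line_no[bad[1L]], " in ", path)
  peak_set(chrom, start, end, source_kind)
}

# Reduce a PeakSet to merged coverage per chromosome as IRanges
.peaks_to_ranges <- function(ps) {
  lapply(split(seq_len(nrow(ps)), ps$chrom), function(i) {
    IRanges::reduce(IRanges::IRanges(start = ps$start[i] + 1L, end = ps$end[i]))
  })
}

.ranges_to_df <- function(by_chrom) {
  out <- lapply(names(by_chrom), function(ch) {
    r <- by_chrom[[ch]]
    if (length(r) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intersect two peak sets
#'
#' Returns the intervals covered by at least one peak of `a` and at least one
#' peak of `b` (base-level AND of the two coverage masks); touching or
#' overlapping output intervals are merged. Overlap is half-open: peaks that
#' merely abut do not intersect.
#'
#' @param a,b `PeakSet` objects.
#' @param source_kind source kind assigned to the result (defaults to `a`'s).
#' @return a `PeakSet` (possibly empty).
#' @export
intersect_peaks <- function(a, b, source_kind = attr(a, "source_kind")) {
  ra <- .peaks_to_ranges(a)
  rb <- .peaks_to_ranges(b)
  common <- intersect(names(ra), names(rb))
  hits <- lapply(common, function(ch) IRanges::intersect(ra[[ch]], rb[[ch]]))
  names(hits) <- common
  df <- .ranges_to_df(hits)
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    return(structure(out, class = c("PeakSet", "data.frame"),
                     source_kind = source_kind))
  }
  peak_set(df$chrom, df$start, df$end, source_kind)
}

#' Construct a labeled genomic region table
#'
#' @param chrom,start,end vectors in 0-based half-open coordinates.
#' @param label one of `"positive"`, `"negative"`, `"unknown"` per region.
#' @return data.frame of class `GenomicRegionList`.
#' @export
genomic_regions <- function(chrom, start, end,
                            label = rep("unknown", length(chrom))) {
  assert_that(all(label %in% c("positive", "negative", "unknown")),
              "label must be positive/negative/unknown")
  assert_that(all(end > start), "region end must exceed start")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  structure(df, class = c("GenomicRegionList", "data.frame"))
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab/space-delimited file: chromosome name, length in bp.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "chrom.sizes needs two columns")
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

# Standardize an interval to exactly `len` bp: anchor at the midpoint, expand
# symmetrically, then shift back inside [0, chrom_len) without shrinking.
.standardize_region <- function(chrom, start, end, len, chrom_sizes = NULL) {
  mid <- floor((start + end) / 2)
  s <- mid - len %/% 2L
  e <- s + len
  if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
    cl <- chrom_sizes[[chrom]]
    if (e > cl) { e <- cl; s <- e - len }
  }
  if (s < 0L) { s <- 0L; e <- len }
  c(as.integer(s), as.integer(e))
}

#' Label candidate enhancer regions
#'
#' Candidates are the intersection of STARR-seq and DNase-seq peak coverage.
#' A candidate that overlaps (>= 1 bp) any ChIP-seq peak (H3K27ac, H3K4me3,
#' H3K4me1 or H3K9ac) is called an enhancer (positive). Each positive is
#' standardized to exactly `region_length` bp anchored at the candidate
#' midpoint.
#'
#' @param starr,dnase `PeakSet` objects.
#' @param chip list of one or more ChIP-seq `PeakSet` objects.
#' @param region_length standardized sample length in bp (default 4000).
#' @param chrom_sizes optional named vector used to clip regions at
#'   chromosome ends (length is preserved by shifting).
#' @return `GenomicRegionList` of positive regions.
#' @export
label_regions <- function(starr, dnase, chip, region_length = 4000L,
                          chrom_sizes = NULL) {
  assert_that(is.list(chip) && length(chip) >= 1L,
              "need at least one ChIP-seq PeakSet")
  cand <- intersect_peaks(starr, dnase)
  if (nrow(cand) == 0L) {
    warning("no STARR/DNase overlap candidates found")
    return(genomic_regions(character(0), integer(0), integer(0), character(0)))
  }
  all_chip <- do.call(rbind, lapply(chip, function(p)
    as.data.frame(p)[c("chrom", "start", "end")]))
  chip_cov <- .peaks_to_ranges(
    peak_set(all_chip$chrom, all_chip$start, all_chip$end, "H3K27ac"))
  keep <- logical(nrow(cand))
  for (ch in unique(cand$chrom)) {
    idx <- which(cand$chrom == ch)
    if (!ch %in% names(chip_cov)) next
    ir <- IRanges::IRanges(start = cand$start[idx] + 1L, end = cand$end[idx])
    ov <- IRanges::countOverlaps(ir, chip_cov[[ch]]) > 0L
    keep[idx] <- ov
  }
  pos <- cand[keep, , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no candidate overlaps a ChIP-seq peak")
    return(genomic_regions(character(0), integer(0), integer(0), character(0)))
  }
  coords <- t(mapply(.standardize_region, pos$chrom, pos$start, pos$end,
                     MoreArgs = list(len = as.integer(region_length),
                                     chrom_sizes = chrom_sizes)))
  genomic_regions(pos$chrom, coords[, 1L], coords[, 2L],
                  rep("positive", nrow(pos)))
}

#' Randomly sample negative (non-enhancer) regions
#'
#' Draws fixed-length regions uniformly from the genome, rejecting any that
#' overlaps a positive region by >= 1 bp. Deterministic given `seed`.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param positives `GenomicRegionList` of enhancer regions to avoid.
#' @param n number of negatives to draw (the conventional design ratio is
#'   10 negatives per positive).
#' @param seed integer seed.
#' @param region_length region length in bp (default 4000).
#' @param max_tries placement attempts before giving up (default 1000 * n).
#' @return `GenomicRegionList` of `n` negative regions.
#' @export
sample_negatives <- function(chrom_sizes, positives, n, seed,
                             region_length = 4000L, max_tries = 1000L * n) {
  assert_that(n >= 0, "n must be >= 0")
  if (n == 0L) return(genomic_regions(character(0), integer(0), integer(0)))
  eligible <- chrom_sizes[chrom_sizes >= region_length]
  assert_that(length(eligible) > 0L, "no chromosome can host a region")
  pos_r <- if (nrow(positives) > 0L) {
    lapply(split(seq_len(nrow(positives)), positives$chrom), function(i)
      IRanges::reduce(IRanges::IRanges(positives$start[i] + 1L, positives$end[i])))
  } else list()
  out_chrom <- character(0); out_start <- integer(0)
  withr::with_seed(seed, {
    tries <- 0L
    w <- as.numeric(eligible - region_length + 1L)
    while (length(out_start) < n && tries < max_tries) {
      tries <- tries + 1L
      ch <- sample(names(eligible), 1L, prob = w)
      s <- sample.int(eligible[[ch]] - region_length + 1L, 1L) - 1L
      ir <- IRanges::IRanges(s + 1L, s + region_length)
      clash <- ch %in% names(pos_r) &&
        IRanges::countOverlaps(ir, pos_r[[ch]]) > 0L
      if (!clash) {
        out_chrom <- c(out_chrom, ch)
        out_start <- c(out_start, s)
      }
    }
  })
  if (length(out_start) < n)
    stop2("could only place ", length(out_start), " of ", n,
          " negative regions after ", max_tries, " attempts")
  genomic_regions(out_chrom, out_start, out_start + region_length,
                  rep("negative", n))
}
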