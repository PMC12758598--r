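# Synthetic data generators. They emulate the structure of the real inputs
# (enriched signal bumps over background for positive regions, 4000 bp
# sequences with a planted motif-dense enhancer) so every pipeline stage is
# testable without external downloads.

#' Simulation configuration
#'
#' @param seed master seed; all generators are bit-reproducible given it.
#' @param n_pos number of positive regions.
#' @param n_neg number of negatives (default `10 * n_pos`, the conventional
#'   1:10 class ratio).
#' @param region_length sample length in bp (default 4000).
#' @param bin_size signal bin width in bp (default 10, giving 400 bins).
#' @param enrichment_height peak height of the positive-class signal bump,
#'   in the same arbitrary units as the background.
#' @param bump_width bump full width at half maximum-ish scale in bp
#'   (Gaussian sd = bump_width / 2).
#' @param background_level flat background signal level.
#' @param noise_sigma Gaussian noise sd added to every bin.
#' @param signal_kinds signals to simulate (bump planted in all of them).
#' @param motif DNA motif planted densely inside synthetic enhancers.
#' @param motif_density expected motif copies per 100 bp of enhancer.
#' @param enhancer_length planted enhancer length in bp (multiple of 50,
#'   between 200 and the region length).
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_pos = 20L, n_neg = 10L * n_pos,
                       region_length = 4000L, bin_size = 10L,
                       enrichment_height = 3, bump_width = 1000L,
                       background_level = 0.5, noise_sigma = 0.3,
                       signal_kinds = c("DNase", "H3K27ac"),
                       motif = "GATTACAGGC", motif_density = 4,
                       enhancer_length = 600L) {
  assert_that(n_pos >= 1L && n_neg >= 0L, "need n_pos >= 1, n_neg >= 0")
  assert_that(region_length %% bin_size == 0L,
              "region_length must be divisible by bin_size")
  assert_that(enhancer_length %% 50L == 0L, "enhancer_length must be a multiple of 50")
  assert_that(enhancer_length >= 200L && enhancer_length <= region_length,
              "enhancer_length must be in [200, region_length]")
  assert_that(enrichment_height >= 0 && background_level >= 0 && noise_sigma >= 0,
              "rates must be >= 0")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a binned-signal classification dataset
#'
#' Positive samples carry a Gaussian-shaped enrichment bump (height
#' `enrichment_height`, sd `bump_width / 2`, centered mid-region) on top of
#' the flat background in every configured signal; negatives are background
#' only. Gaussian noise of sd `noise_sigma` is added to all bins. Features
#' are binned to `region_length / bin_size` values per signal, matching the
#' real pipeline's layout.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a `SignalMatrix`) and `truth` (bump center
#'   and per-signal heights per positive).
#' @export
gen_signal_dataset <- function(cfg) {
  n_bins <- cfg$region_length %/% cfg$bin_size
  n <- cfg$n_pos + cfg$n_neg
  centers <- (seq_len(n_bins) - 0.5) * cfg$bin_size
  mid <- cfg$region_length / 2
  bump <- cfg$enrichment_height * exp(-0.5 * ((centers - mid) / (cfg$bump_width / 2))^2)
  X <- withr::with_seed(cfg$seed, {
    blocks <- lapply(cfg$signal_kinds, function(s) {
      base <- matrix(cfg$background_level, n, n_bins)
      base[seq_len(cfg$n_pos), ] <- base[seq_len(cfg$n_pos), ] +
        matrix(bump, cfg$n_pos, n_bins, byrow = TRUE)
      base + matrix(rnorm(n * n_bins, 0, cfg$noise_sigma), n, n_bins)
    })
    do.call(cbind, blocks)
  })
  y <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  regions <- genomic_regions(
    chrom = paste0("sim", seq_len(n)), start = rep(0L, n),
    end = rep(cfg$region_length, n),
    label = ifelse(y == 1L, "positive", "negative"))
  truth <- data.frame(region = seq_len(cfg$n_pos), bump_center = mid,
                      height = cfg$enrichment_height)
  list(matrix = signal_matrix(X, y, cfg$signal_kinds, cfg$bin_size, regions),
       truth = truth)
}

.random_dna <- function(n) paste(sample(KMER_ALPHABET, n, replace = TRUE),
                                 collapse = "")

# Plant motif copies into a sequence segment. Copies are evenly spaced (with
# a small jitter) so motif density is homogeneous across the segment: every
# window fully inside sees the same density, windows straddling the edge see
# a density proportional to their overlap.
.plant_motifs <- function(seq_chars, seg_start, seg_len, motif, density) {
  m <- nchar(motif)
  n_copies <- max(0L, round(density * seg_len / 100))
  if (n_copies == 0L || seg_len < m) return(seq_chars)
  slots <- round(seq(0, seg_len - m, length.out = n_copies))
  jitter_max <- max(1, floor((seg_len - m) / max(1, n_copies - 1) / 4))
  pos <- slots + sample.int(jitter_max, n_copies, replace = TRUE) - 1L
  pos <- pmin(pmax(pos, 0L), seg_len - m) + seg_start
  mc <- strsplit(motif, "")[[1L]]
  for (p in pos) seq_chars[p:(p + m - 1L)] <- mc
  seq_chars
}

#' Simulate localization regions with planted enhancers
#'
#' Each record is a `region_length` DNA sequence of uniform-ACGT background
#' with one motif-dense enhancer segment of `enhancer_length` bp placed at a
#' random 50 bp-aligned offset. The truth table records the planted interval.
#'
#' @param cfg a [sim_config()].
#' @param n number of regions (default `n_pos`).
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame: name, enh_start, enh_end in 0-based region offsets).
#' @export
gen_localization_dataset <- function(cfg, n = cfg$n_pos) {
  withr::with_seed(child_seed(cfg$seed, 101L), {
    n_slots <- (cfg$region_length - cfg$enhancer_length) %/% 50L + 1L
    starts <- (sample.int(n_slots, n, replace = TRUE) - 1L) * 50L
    seqs <- character(n)
    for (i in seq_len(n)) {
      chars <- sample(KMER_ALPHABET, cfg$region_length, replace = TRUE)
      chars <- .plant_motifs(chars, starts[i] + 1L, cfg$enhancer_length,
                             cfg$motif, cfg$motif_density)
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- paste0("region_", seq_len(n))
    list(sequences = seqs,
         truth = data.frame(name = names(seqs), enh_start = starts,
                            enh_end = starts + cfg$enhancer_length,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a labeled window training set
#'
#' Draws 200 bp windows from synthetic localization regions and labels them
#' by the >= 50% enhancer-overlap rule: positives are sampled fully inside a
#' planted enhancer segment, negatives anywhere with less than 50% overlap
#' (including partially overlapping flank windows, which forces a scorer to
#' discriminate motif density rather than mere motif presence). Classes are
#' balanced by default. Windows are embedded with the supplied embedder
#' (k-mer frequencies by default).
#'
#' @param cfg a [sim_config()].
#' @param n_per_class windows per class (default 250).
#' @param embedder an `Embedder` (default `kmer_embedder(cfg_k)` with k = 6).
#' @param window window length in bp (default 200).
#' @return list with `X` (embedded features), `y` (labels) and `truth`.
#' @export
gen_window_training_set <- function(cfg, n_per_class = 250L,
                                    embedder = kmer_embedder(6L),
                                    window = 200L) {
  loc <- gen_localization_dataset(cfg, n = max(4L, ceiling(n_per_class / 8L)))
  withr::with_seed(child_seed(cfg$seed, 102L), {
    pick_window <- function(want_pos) {
      repeat {
        i <- sample.int(length(loc$sequences), 1L)
        if (want_pos) {
          # fully inside the planted enhancer segment
          lo <- loc$truth$enh_start[i]
          hi <- loc$truth$enh_end[i] - window
          if (hi < lo) next
          off <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          return(c(i, off))
        }
        # half the negatives are flank windows with 1..49% overlap so the
        # scorer sees the full overlap margin, not only zero-motif windows
        if (runif(1) < 0.5) {
          side <- sample(c(-1L, 1L), 1L)
          ov_target <- sample.int(window %/% 2L - 1L, 1L)   # 1..99 bp overlap
          off <- if (side < 0L) loc$truth$enh_start[i] - window + ov_target
                 else loc$truth$enh_end[i] - ov_target
          if (off < 0L || off > cfg$region_length - window) next
        } else {
          off <- sample.int(cfg$region_length - window + 1L, 1L) - 1L
        }
        ov <- max(0L, min(off + window, loc$truth$enh_end[i]) -
                    max(off, loc$truth$enh_start[i]))
        if (ov < window / 2) return(c(i, off))
      }
    }
    draws <- rbind(
      t(replicate(n_per_class, pick_window(TRUE))),
      t(replicate(n_per_class, pick_window(FALSE))))
    X <- t(apply(draws, 1L, function(d)
      kmer_embed(substr(loc$sequences[d[1L]], d[2L] + 1L, d[2L] + window),
                 embedder$k)))
    y <- c(rep(1L, n_per_class), rep(0L, n_per_class))
    list(X = X, y = y, truth = loc$truth)
  })
}

#' Write a synthetic genome's pipeline inputs to disk
#'
#' Emits the same plain-text formats the real pipeline reads: BED peaks for
#' STARR/DNase/ChIP assays around planted enhancers, bedGraph tracks with
#' enrichment bumps, a chrom.sizes file and a FASTA of localization regions.
#' This lets synthetic runs exercise the real file-reading path end to end.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named list of written file paths.
#' @export
write_sim_files <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- cfg$region_length
  spacing <- 4L * rl
  chrom_len <- (cfg$n_pos + 2L) * spacing
  centers <- spacing * seq_len(cfg$n_pos)
  paths <- list()
  withr::with_seed(child_seed(cfg$seed, 103L), {
    jit <- function(w) as.integer(round(runif(cfg$n_pos, -w / 4, w / 4)))
    mk_bed <- function(file, half_width) {
      j1 <- jit(half_width); j2 <- jit(half_width)
      df <- data.frame(chrom = "chrSim", start = centers - half_width + j1,
                       end = centers + half_width + j2)
      write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      file.path(dir, file)
    }
    paths$starr <- mk_bed("starr.bed", 800L)
    paths$dnase <- mk_bed("dnase.bed", 600L)
    paths$chip <- mk_bed("h3k27ac.bed", 1000L)
    # bedGraph: background everywhere, bump bins around each center
    step <- cfg$bin_size
    bg <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), value = numeric(0))
    for (ctr in centers) {
      s <- seq.int(ctr - rl / 2, ctr + rl / 2 - step, by = step)
      v <- cfg$background_level +
        cfg$enrichment_height * exp(-0.5 * ((s + step / 2 - ctr) / (cfg$bump_width / 2))^2)
      bg <- rbind(bg, data.frame(chrom = "chrSim", start = s, end = s + step,
                                 value = round(v, 4)))
    }
    paths$bedgraph <- file.path(dir, "dnase.bedgraph")
    write.table(bg, paths$bedgraph, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  })
  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  writeLines(paste0("chrSim\t", chrom_len), paths$chrom_sizes)
  loc <- gen_localization_dataset(cfg)
  paths$fasta <- file.path(dir, "regions.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(loc$sequences), paths$fasta)
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(loc$truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
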