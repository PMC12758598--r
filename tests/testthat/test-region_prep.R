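test_that("read_peaks parses, sorts and validates BED input", {
  p <- write_bed(data.frame(c("chr2", "chr1", "chr1"), c(50L, 30L, 5L),
                            c(80L, 60L, 20L)))
  ps <- read_peaks(p, "DNase")
  expect_s3_class(ps, "PeakSet")
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$start, c(5L, 30L, 50L))
  expect_identical(attr(ps, "source_kind"), "DNase")

  bad <- write_bed(data.frame("chr1", c(10L, 50L), c(20L, 40L)))
  expect_error(read_peaks(bad), "line 2")
  short <- tempfile(); writeLines(c("chr1\t1\t5", "chr1\t9"), short)
  expect_error(read_peaks(short), "line 2")
  expect_error(read_peaks(tempfile()), "not found")
})

test_that("intersect_peaks handles the half-open boundary cases", {
  a <- peak_set("chr1", 0L, 10L)
  b <- peak_set("chr1", 5L, 15L, "DNase")
  out <- intersect_peaks(a, b)
  expect_equal(as.data.frame(out)[c("start", "end")],
               data.frame(start = 5L, end = 10L))
  # touching intervals share no base
  expect_equal(nrow(intersect_peaks(peak_set("chr1", 0L, 10L),
                                    peak_set("chr1", 10L, 20L, "DNase"))), 0L)
})

test_that("intersect_peaks equals the per-base AND oracle on random peaks", {
  for (rep in 1:20) {
    withr::with_seed(1000 + rep, {
      a <- random_peaks(20L, 1000L)
      b <- random_peaks(20L, 1000L, source_kind = "DNase")
    })
    out <- intersect_peaks(a, b)
    expected <- mask_to_intervals(coverage_mask(a, "chrT", 1000L) &
                                  coverage_mask(b, "chrT", 1000L))
    got <- as.data.frame(out)[c("start", "end")]
    rownames(got) <- rownames(expected) <- NULL
    expect_equal(got, expected, info = paste("rep", rep))
  }
})

test_that("label_regions applies the ChIP overlap rule and standardizes to 4000 bp", {
  starr <- peak_set("chr1", 100L, 300L)
  dnase <- peak_set("chr1", 0L, 5000L, "DNase")
  chip_hit <- peak_set("chr1", 250L, 400L, "H3K27ac")
  pos <- label_regions(starr, dnase, list(chip_hit),
                       chrom_sizes = c(chr1 = 100000L))
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$end - pos$start, 4000L)
  # candidate midpoint is 200; clipping at the chromosome start shifts to 0
  expect_equal(pos$start, 0L)
  expect_equal(pos$label, "positive")

  chip_miss <- peak_set("chr1", 1000L, 1100L, "H3K27ac")
  expect_warning(none <- label_regions(starr, dnase, list(chip_miss)),
                 "no candidate")
  expect_equal(nrow(none), 0L)
})

test_that("label_regions recovers planted enhancers (per-base oracle)", {
  centers <- c(10000L, 30000L, 50000L, 70000L, 90000L)
  starr <- peak_set(rep("chr1", 6), c(centers - 400L, 95000L),
                    c(centers + 400L, 95200L))
  dnase <- peak_set(rep("chr1", 5), centers - 300L, centers + 300L, "DNase")
  chip <- peak_set(rep("chr1", 5), centers - 100L, centers + 100L, "H3K27ac")
  pos <- label_regions(starr, dnase, list(chip),
                       chrom_sizes = c(chr1 = 200000L))
  expect_equal(nrow(pos), 5L)
  expect_true(all(pos$end - pos$start == 4000L))
  # candidates by oracle: STARR AND DNase coverage, overlapping ChIP
  cand <- mask_to_intervals(coverage_mask(starr, "chr1", 200000L) &
                            coverage_mask(dnase, "chr1", 200000L))
  chip_mask <- coverage_mask(chip, "chr1", 200000L)
  hits <- cand[vapply(seq_len(nrow(cand)), function(i)
    any(chip_mask[(cand$start[i] + 1):cand$end[i]]), logical(1)), ]
  mid <- floor((hits$start + hits$end) / 2)
  expect_equal(pos$start, as.integer(mid - 2000L))
})

test_that("sample_negatives avoids positives, honors ratio, is deterministic", {
  sizes <- c(chrA = 300000L, chrB = 200000L)
  pos <- genomic_regions(c("chrA", "chrB"), c(10000L, 50000L),
                         c(14000L, 54000L), rep("positive", 2))
  neg <- sample_negatives(sizes, pos, 20L, seed = 5L)
  expect_equal(nrow(neg), 20L)
  expect_true(all(neg$end - neg$start == 4000L))
  for (i in seq_len(nrow(neg))) {
    same <- pos[pos$chrom == neg$chrom[i], , drop = FALSE]
    if (nrow(same) > 0L)
      expect_true(all(neg$end[i] <= same$start | neg$start[i] >= same$end))
  }
  expect_identical(sample_negatives(sizes, pos, 20L, seed = 5L), neg)
  expect_false(identical(sample_negatives(sizes, pos, 20L, seed = 6L), neg))
  expect_equal(nrow(sample_negatives(sizes, pos, 0L, seed = 1L)), 0L)
  # impossible placement: genome fully covered by positives
  tiny <- c(chrC = 4000L)
  blocked <- genomic_regions("chrC", 0L, 4000L, "positive")
  expect_error(sample_negatives(tiny, blocked, 3L, seed = 1L, max_tries = 50L),
               "0 of 3")
})

test_that("bin_signal matches the per-base expansion oracle", {
  # constant track
  tr <- signal_track("chr1", 0L, 4000L, 2.5, "DNase")
  reg <- genomic_regions("chr1", 0L, 4000L)
  v <- bin_signal(tr, reg)
  expect_length(v, 400L)
  expect_true(all(v == 2.5))

  # random step track over a 100 bp region, including uncovered gaps
  withr::with_seed(9, {
    starts <- c(0L, 15L, 40L, 70L)
    ends <- c(10L, 35L, 60L, 95L)
    vals <- round(runif(4, 0, 5), 2)
  })
  tr2 <- signal_track(rep("chr1", 4), starts, ends, vals, "H3K27ac")
  reg2 <- genomic_regions("chr1", 0L, 100L)
  base <- numeric(100)
  for (i in 1:4) base[(starts[i] + 1):ends[i]] <- vals[i]
  expect_equal(bin_signal(tr2, reg2, 10L),
               colMeans(matrix(base, nrow = 10)))
  # mean of bin means equals per-base mean under complete equal bins
  expect_equal(mean(bin_signal(tr2, reg2, 10L)), mean(base))
  expect_error(bin_signal(tr2, genomic_regions("chr1", 0L, 95L), 10L),
               "not divisible")
})

test_that("build_matrix concatenates 400-length blocks per signal", {
  reg <- genomic_regions(c("chr1", "chr1"), c(0L, 4000L), c(4000L, 8000L),
                         c("positive", "negative"))
  kinds <- c("DNase", "H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac")
  tracks <- lapply(seq_along(kinds), function(i)
    signal_track("chr1", 0L, 8000L, i, kinds[i]))
  names(tracks) <- kinds
  m2 <- build_matrix(reg, tracks, c("DNase", "H3K27ac"))
  expect_equal(ncol(m2$X), 800L)
  m5 <- build_matrix(reg, tracks, kinds)
  expect_equal(ncol(m5$X), 2000L)
  expect_equal(m5$y, c(1L, 0L))
  # composition: single row equals bin_signal output, in declared order
  expect_equal(m5$X[1L, 401:800], rep(2, 400))
  expect_equal(unname(m5$X[1L, 1:400]),
               bin_signal(tracks$DNase, reg[1L, , drop = FALSE]))
  expect_error(build_matrix(reg, tracks["DNase"], c("DNase", "H3K9ac")),
               "H3K9ac")
})

test_that("add_gaussian_noise has the stated moments and determinism", {
  m <- signal_matrix(matrix(1, 200, 2000), rep(c(0L, 1L), 100), c("DNase", "H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac"))
  expect_identical(add_gaussian_noise(m, 0, seed = 1L), m)
  m9 <- add_gaussian_noise(m, 0.9, seed = 1L)
  expect_equal(sd(m9$X - m$X), 0.9, tolerance = 0.02)
  expect_equal(m9$y, m$y)
  expect_identical(add_gaussian_noise(m, 0.9, seed = 1L)$X, m9$X)
  expect_error(add_gaussian_noise(m, -0.1, seed = 1L), "sigma")
})

test_that("signal matrix round-trips through TSV + JSON sidecar", {
  reg <- genomic_regions(c("c1", "c2"), c(0L, 100L), c(100L, 200L),
                         c("positive", "negative"))
  m <- signal_matrix(matrix(rnorm(2 * 20), 2, 20), c(1L, 0L),
                     c("DNase", "H3K27ac"), 10L, reg)
  path <- tempfile(fileext = ".tsv")
  write_signal_matrix(m, path)
  m2 <- read_signal_matrix(path)
  expect_equal(m2$X, m$X, tolerance = 1e-12)
  expect_equal(m2$y, m$y)
  expect_equal(m2$signal_kinds, m$signal_kinds)
  expect_equal(as.data.frame(m2$region_index), as.data.frame(m$region_index))
})
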