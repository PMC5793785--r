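# a 120-nt toy chromosome with one gene per strand (leader 30 nt, mORF 30 nt)
psite_models <- function() list(toyP = toy_plus_model(), toyM = toy_minus_model())

test_that("P-site assignment arithmetic is strand-aware", {
  models <- psite_models()
  # one 28-mer on + at genomic start 100 would miss the toy gene; use start 20:
  # 5' end 20, offset 12 -> P-site at genomic 32 -> transcript coord 22
  fp <- data.frame(chrom = "chr1", strand = "+", start = 20L, end = 48L,
                   qwidth = 28L)
  tr <- assign_psites(fp, c(`28` = 12L), models)
  expect_equal(which(tr$toyP == 1L) - 1L, 22L)
  expect_equal(sum(tr$toyP), 1L)
  # minus strand: alignment end at genomic 76 (half-open), 5' end = 75,
  # offset 12 -> P-site at genomic 63 -> transcript coord 90 - 63 = 27
  fpm <- data.frame(chrom = "chr1", strand = "-", start = 48L, end = 76L,
                    qwidth = 28L)
  trm <- assign_psites(fpm, c(`28` = 12L), models)
  expect_equal(which(trm$toyM == 1L) - 1L, 27L)
})

test_that("reads with lengths absent from the offset table are dropped and counted", {
  models <- psite_models()
  fp <- data.frame(chrom = "chr1", strand = "+", start = c(20L, 21L),
                   end = c(48L, 56L), qwidth = c(28L, 35L))
  expect_message(tr <- assign_psites(fp, c(`28` = 12L), models), "dropped")
  expect_equal(attr(tr, "n_dropped_length"), 1L)
  expect_equal(sum(tr$toyP), 1L)
})

test_that("empty alignments give all-zero tracks of the right length", {
  models <- psite_models()
  fp <- data.frame(chrom = character(0), strand = character(0),
                   start = integer(0), end = integer(0), qwidth = integer(0))
  tr <- assign_psites(fp, default_offsets(), models)
  expect_equal(length(tr$toyP), transcript_length(models$toyP))
  expect_true(all(tr$toyP == 0L) && all(tr$toyM == 0L))
})

test_that("total assigned P-sites equal retained in-transcript reads (conservation)", {
  models <- psite_models()
  set.seed(3)
  n <- 200
  fp <- data.frame(chrom = "chr1", strand = "+",
                   start = sample(0:80, n, TRUE), qwidth = 28L)
  fp$end <- fp$start + 28L
  tr <- assign_psites(fp, c(`28` = 12L), models["toyP"])
  expect_equal(sum(tr$toyP), n - attr(tr, "n_outside"))
})

test_that("a strand-flipped locus yields the identical transcript-coordinate track", {
  # equivalent read stacks on the two toy genes: P-site at transcript coord 10
  models <- psite_models()
  # +: genomic p = distal(10) + 10 = 20; read 5' end = 20 - 12 = 8
  fp_p <- data.frame(chrom = "chr1", strand = "+", start = 8L, end = 36L,
                     qwidth = 28L)
  # -: genomic p = distal(90) - 10 = 80; 5' end = 80 + 12 = 92 -> end = 93
  fp_m <- data.frame(chrom = "chr1", strand = "-", start = 65L, end = 93L,
                     qwidth = 28L)
  tp <- assign_psites(fp_p, c(`28` = 12L), models["toyP"])$toyP
  tm <- assign_psites(fp_m, c(`28` = 12L), models["toyM"])$toyM
  expect_equal(tp, tm)
  expect_equal(which(tp == 1L) - 1L, 10L)
})

test_that("orf_frame_fraction measures 3-nt periodicity", {
  track <- integer(30)
  track[seq(10, 21, by = 3)] <- 4L          # only codon-start positions
  expect_equal(orf_frame_fraction(track, 9L, 12L), 1.0)
  uni <- rep(2L, 30)
  expect_equal(orf_frame_fraction(uni, 9L, 12L), 1 / 3)
  one_codon <- integer(12); one_codon[4:6] <- c(3L, 1L, 2L)
  expect_equal(orf_frame_fraction(one_codon, 3L, 3L), 0.5)
  expect_true(is.na(orf_frame_fraction(integer(12), 0L, 6L)))
  expect_error(orf_frame_fraction(uni, 0L, 4L))
})

test_that("BAM round trip through Rsamtools recovers the alignments", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:120",
    paste("r1", 0, "chr1", 21, 60, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),
    paste("r2", 16, "chr1", 49, 60, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),
    paste("r3", 4, "chr1", 10, 60, "28M", "*", 0, 0,   # unmapped: excluded
          strrep("A", 28), "*", sep = "\t")),
    sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  fp <- read_footprints(bam)
  expect_equal(nrow(fp), 2L)
  expect_equal(fp$start, c(20L, 48L))       # SAM 1-based -> 0-based
  expect_equal(fp$end, c(48L, 76L))
  expect_equal(fp$strand, c("+", "-"))
})

test_that("offset calibration recovers the true offset from start-codon pileups", {
  models <- psite_models()
  # reads whose P-site at offset 12 lands exactly on the mORF start (genomic 40)
  fp <- data.frame(chrom = "chr1", strand = "+",
                   start = rep(28L, 20), end = rep(56L, 20), qwidth = 28L)
  ot <- calibrate_offsets(fp, models["toyP"], lengths = 28)
  expect_equal(ot[["28"]], 12L)
})
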