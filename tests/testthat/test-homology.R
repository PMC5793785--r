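test_that("jaccard index counts nucleotide overlap over union", {
  expect_equal(jaccard_index(c(0L, 10L), c(0L, 10L)), 1)
  expect_equal(jaccard_index(c(0L, 10L), c(20L, 30L)), 0)
  expect_equal(jaccard_index(c(0L, 10L), c(5L, 15L)), 5 / 15)
  # symmetry
  expect_equal(jaccard_index(c(3L, 9L), c(5L, 20L)),
               jaccard_index(c(5L, 20L), c(3L, 9L)))
})

test_that("an identical substring aligns perfectly with the matrix match score", {
  set.seed(61)
  tl <- random_dna(80)
  uorf <- substr(tl, 21, 38)
  res <- align_uorf_to_tl(uorf, tl, n_shuffles = 0)
  m <- hoxd70_matrix()
  bases <- strsplit(uorf, "")[[1]]
  expect_equal(res$score, sum(m[cbind(bases, bases)]))
  expect_equal(res$mapped_start, 20L)
  expect_equal(res$mapped_end, 38L)
  # a reversed (not complemented) uORF cannot score as well
  rev_uorf <- paste(rev(bases), collapse = "")
  res_rev <- align_uorf_to_tl(rev_uorf, tl, n_shuffles = 0)
  expect_lt(res_rev$score, res$score)
})

test_that("random uORFs against unrelated leaders have near-zero Z-scores", {
  set.seed(62)
  zs <- vapply(1:5, function(i) {
    align_uorf_to_tl(random_dna(24), random_dna(100),
                     n_shuffles = 50, seed = i)$z_score
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
})

test_that("sequence homology pairs planted identical uORFs with Jaccard 1", {
  set.seed(63)
  tl <- random_dna(70)
  uorf_seq <- "ATGCATCATCGGTGA"
  substr(tl, 31, 45) <- uorf_seq
  calls <- data.frame(gene_id = "g1", start_pos = 30L, stop_pos = 44L,
                      start_codon = "ATG", length_nt = 15L,
                      overlaps_morf = FALSE)
  pairs <- sequence_homologs(calls, calls,
                             data.frame(gene_a = "g1", gene_b = "g1"),
                             c(g1 = tl), c(g1 = tl), n_shuffles = 20, seed = 1)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$jaccard, 1)
  expect_equal(pairs$class, "sequence")
})

test_that("overlap below the Jaccard threshold is not a sequence homolog", {
  tl <- strrep("C", 80)
  uorf_seq <- "ATGAAGAAGAAGTGA"                 # 15 nt
  tl_a <- tl; substr(tl_a, 31, 45) <- uorf_seq
  # in species B the called interval is shifted so overlap/union = 0.5
  tl_b <- tl; substr(tl_b, 31, 45) <- uorf_seq
  calls_a <- data.frame(gene_id = "g1", start_pos = 30L, stop_pos = 44L,
                        start_codon = "ATG", length_nt = 15L,
                        overlaps_morf = FALSE)
  calls_b <- transform(calls_a, start_pos = 35L, stop_pos = 49L)
  gp <- data.frame(gene_a = "g1", gene_b = "g1")
  got <- sequence_homologs(calls_a, calls_b, gp, c(g1 = tl_a), c(g1 = tl_b),
                           threshold = 0.6, n_shuffles = 0)
  expect_equal(nrow(got), 0L)   # jaccard 10/20 = 0.5 < 0.6
  got0 <- sequence_homologs(calls_a, calls_b, gp, c(g1 = tl_a), c(g1 = tl_b),
                            threshold = 0.0, n_shuffles = 0)
  expect_equal(nrow(got0), 1L)
  expect_equal(got0$jaccard, 0.5)
})

test_that("positional homology applies the +/- 5 nt OR rule relative to the mORF", {
  ll <- c(g1 = 100L)
  gp <- data.frame(gene_a = "g1", gene_b = "g1")
  mk <- function(start, stop) data.frame(gene_id = "g1", start_pos = start,
                                         stop_pos = stop, start_codon = "ATG",
                                         length_nt = stop - start + 1L,
                                         overlaps_morf = FALSE)
  # starts 50 and 52 nt upstream: |2| <= 5 pairs
  a <- mk(50L, 70L); b <- mk(48L, 72L)
  expect_equal(nrow(position_homologs(a, b, gp, ll, ll)), 1L)
  # both distances differ by 6: no pair
  b6 <- mk(44L, 64L)
  expect_equal(nrow(position_homologs(a, b6, gp, ll, ll)), 0L)
  # starts differ by 9 but stops by 1: OR semantics pairs them
  b9 <- mk(41L, 69L)
  expect_equal(nrow(position_homologs(a, b9, gp, ll, ll)), 1L)
  # AND semantics refuses the same pair
  expect_equal(nrow(position_homologs(a, b9, gp, ll, ll, rule = "and")), 0L)
})

test_that("sequence classification takes precedence over positional", {
  set.seed(64)
  tl <- random_dna(90)
  uorf_seq <- "TTGCGATCGTACGGATAA"               # 18 nt
  substr(tl, 41, 58) <- uorf_seq
  calls <- data.frame(gene_id = "g1", start_pos = 40L, stop_pos = 57L,
                      start_codon = "TTG", length_nt = 18L,
                      overlaps_morf = FALSE)
  gp <- data.frame(gene_a = "g1", gene_b = "g1")
  # identical species: the pair satisfies both definitions
  both <- classify_homologs(calls, calls, gp, c(g1 = tl), c(g1 = tl),
                            n_shuffles = 10, seed = 2)
  expect_equal(nrow(both), 1L)
  expect_equal(both$class, "sequence")
})

test_that("divergent-sequence pairs at small positional shifts become positional homologs", {
  set.seed(65)
  # same leader lengths, unrelated sequences, start distance differs by 3
  tl_a <- random_dna(100); tl_b <- random_dna(100)
  calls_a <- data.frame(gene_id = "g1", start_pos = 40L, stop_pos = 57L,
                        start_codon = "ATG", length_nt = 18L,
                        overlaps_morf = FALSE)
  calls_b <- transform(calls_a, start_pos = 43L, stop_pos = 60L)
  gp <- data.frame(gene_a = "g1", gene_b = "g1")
  got <- classify_homologs(calls_a, calls_b, gp, c(g1 = tl_a), c(g1 = tl_b),
                           n_shuffles = 10, seed = 3)
  expect_equal(nrow(got), 1L)
  expect_equal(got$class, "position")
})

test_that("triplet counting finds components spanning three species", {
  pAB <- data.frame(gene_a = "g1", gene_b = "g1", idx_a = 1L, idx_b = 1L,
                    class = "sequence", jaccard = 1,
                    alignment_score = 100, z_score = 5)
  pBC <- data.frame(gene_a = "g1", gene_b = "g1", idx_a = 1L, idx_b = 1L,
                    class = "sequence", jaccard = 1,
                    alignment_score = 100, z_score = 5)
  res <- homolog_triplets(list(A_B = pAB, B_C = pBC))
  expect_equal(res$n_triplets, 1L)
  # a pair lacking the third species is not a triplet
  res2 <- homolog_triplets(list(A_B = pAB))
  expect_equal(res2$n_triplets, 0L)
})
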