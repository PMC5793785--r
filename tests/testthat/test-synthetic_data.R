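small_cfg <- function(seed = 11, ...) {
  simulation_config(n_genes = 15L, seed = seed, ...)
}

test_that("the generator is deterministic for a fixed config and seed", {
  s1 <- generate_transcriptome(small_cfg())
  s2 <- generate_transcriptome(small_cfg())
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a seed is mandatory and a zero planted fraction empties the truth table", {
  expect_error(simulation_config(n_genes = 5), "seed")
  s <- generate_transcriptome(simulation_config(n_genes = 10,
                                                planted_fraction = 0,
                                                seed = 3))
  expect_equal(nrow(s$truth), 0L)
})

test_that("every planted uORF is recovered by the enumerator on its own leader", {
  s <- generate_transcriptome(small_cfg(seed = 21))
  gset <- Biostrings::DNAStringSet(unlist(s$genomes$A))
  for (i in seq_len(nrow(s$truth))) {
    g <- s$truth$gene_id[i]
    m <- s$models$A[[g]]
    cands <- enumerate_candidates(tl_sequence(m, gset),
                                  transcript_sequence(m, gset), gene_id = g)
    hit <- cands[cands$start_pos == s$truth$start_pos[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$stop_pos, s$truth$stop_pos[i])
    expect_equal(hit$start_codon, s$truth$start_codon[i])
  }
})

test_that("zero divergence gives identical leaders and fully shared planted uORFs", {
  cfg <- small_cfg(seed = 31, divergence = 0, shared_fraction = 1)
  s <- generate_transcriptome(cfg)
  ga <- Biostrings::DNAStringSet(unlist(s$genomes$A))
  gb <- Biostrings::DNAStringSet(unlist(s$genomes$B))
  for (g in names(s$models$A)) {
    expect_equal(tl_sequence(s$models$A[[g]], ga),
                 tl_sequence(s$models$B[[g]], gb))
  }
  expect_true(all(s$truth$present_B))
})

test_that("non-shared planted uORFs lose their start codon in the sister species", {
  cfg <- small_cfg(seed = 41, divergence = 0, shared_fraction = 0)
  s <- generate_transcriptome(cfg)
  gb <- Biostrings::DNAStringSet(unlist(s$genomes$B))
  expect_true(all(!s$truth$present_B))
  for (i in seq_len(nrow(s$truth))) {
    g <- s$truth$gene_id[i]
    tl_b <- tl_sequence(s$models$B[[g]], gb)
    codon_b <- substr(tl_b, s$truth$start_pos[i] + 1, s$truth$start_pos[i] + 3)
    expect_false(codon_b %in% uorf_start_codons())
  }
})

test_that("end-seq simulation concentrates signal within the 2-nt jitter", {
  cfg <- simulation_config(n_genes = 4L, max_tss_clusters = 1L, seed = 51,
                           n_species = 1L)
  s <- generate_transcriptome(cfg)
  genome_len <- nchar(s$genomes$A[[1]])
  ends <- simulate_end_seq(s$models$A, genome_len, depth = 1000,
                           background_rate = 0, seed = 5)
  for (m in s$models$A) {
    pl <- ends$tss[[m$strand]]
    tss <- m$tl_isoforms$tss[1]
    near <- pl$pos >= tss - 2 & pl$pos <= tss + 2
    expect_gte(sum(pl$count[near]), 900)
  }
})

test_that("depth zero leaves pure Poisson background", {
  cfg <- simulation_config(n_genes = 3L, seed = 52, n_species = 1L)
  s <- generate_transcriptome(cfg)
  genome_len <- nchar(s$genomes$A[[1]])
  ends <- simulate_end_seq(s$models$A, genome_len, depth = 0,
                           background_rate = 0.05, seed = 6)
  total <- sum(ends$tss[["+"]]$count) + sum(ends$tss[["-"]]$count)
  # expectation 2 strands x 0.05 x genome_len; allow 5 sd
  mu <- 2 * 0.05 * genome_len
  expect_lt(abs(total - mu), 5 * sqrt(mu))
})

test_that("profiling periodicity propagates to the frame fraction of planted uORFs", {
  cfg <- simulation_config(n_genes = 30L, planted_fraction = 1,
                           periodicity = 1 / 3, leader_noise_rate = 0.05,
                           uorf_multiplier = 40, seed = 53, n_species = 1L)
  s <- generate_transcriptome(cfg)
  prof <- simulate_profiling(s$models$A, s$truth, cfg, seed = 7)
  fracs <- c()
  for (i in seq_len(nrow(s$truth))) {
    g <- s$truth$gene_id[i]
    pooled <- Reduce(`+`, prof[[g]]$tracks)
    f <- orf_frame_fraction(pooled, s$truth$start_pos[i],
                            s$truth$stop_pos[i] - s$truth$start_pos[i] + 1L)
    if (!is.na(f)) fracs <- c(fracs, f)
  }
  expect_equal(mean(fracs), 1 / 3, tolerance = 0.08)
})

test_that("profiling replicates are reproducible for a fixed seed", {
  cfg <- small_cfg(seed = 54)
  s <- generate_transcriptome(cfg)
  p1 <- simulate_profiling(s$models$A, s$truth, cfg, seed = 8)
  p2 <- simulate_profiling(s$models$A, s$truth, cfg, seed = 8)
  expect_identical(p1, p2)
  p3 <- simulate_profiling(s$models$A, s$truth, cfg, seed = 9)
  expect_false(identical(p1, p3))
})
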