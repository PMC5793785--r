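# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# write a small FASTA and return its path
write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(names(records), function(n) c(paste0(">", n), records[[n]])))
  writeLines(lines, path)
  path
}

# a simple plus-strand gene: leader "AACGT...", mORF starting at a known
# genomic offset inside a toy chromosome
toy_plus_model <- function() {
  transcript_model("toyP", "chr1", "+", morf_start = 40L, morf_stop = 69L,
                   tss = c(10L, 25L), tss_usage = c(3, 1),
                   pa = 80L, utr3 = c(70L, 85L))
}

toy_minus_model <- function() {
  transcript_model("toyM", "chr1", "-", morf_start = 60L, morf_stop = 31L,
                   tss = c(90L, 75L), tss_usage = c(3, 1),
                   pa = 20L, utr3 = c(15L, 31L))
}

# brute-force enumeration oracle: scan every position, test codon membership,
# walk the frame to the first stop
oracle_enumerate <- function(leader, ctx = leader) {
  ll <- nchar(leader)
  L <- nchar(ctx)
  starts <- uorf_start_codons()
  stops <- stop_codons()
  rows <- list()
  if (ll >= 3) {
    for (p in 0:(ll - 3)) {
      cod <- substr(ctx, p + 1, p + 3)
      if (!cod %in% starts) next
      q <- p + 3
      stop_at <- NA
      while (q + 3 <= L) {
        if (substr(ctx, q + 1, q + 3) %in% stops) { stop_at <- q; break }
        q <- q + 3
      }
      if (is.na(stop_at)) next
      rows[[length(rows) + 1]] <- data.frame(
        start_pos = p, stop_pos = stop_at + 2, start_codon = cod,
        length_nt = stop_at + 2 - p + 1, overlaps_morf = stop_at + 2 >= ll)
    }
  }
  if (!length(rows)) {
    return(data.frame(start_pos = integer(0), stop_pos = integer(0),
                      start_codon = character(0), length_nt = integer(0),
                      overlaps_morf = logical(0)))
  }
  do.call(rbind, rows)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# minimal single-gene gene_data entry for feature/regression tests
toy_gene_data <- function(cands, tracks, rna = NULL, leader_len = 30L) {
  txlen <- length(tracks[[1]])
  if (is.null(rna)) rna <- rep(1L, txlen)
  list(cands = cands, tracks = tracks, rna = rna, leader_len = leader_len)
}
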