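#' Triplet observed/expected ratios between leaders and 3' UTRs
#'
#' Counts overlapping (stride-1) 3-nt windows in each sequence set, converts
#' to frequencies, and reports the ratio of transcript-leader frequency to
#' 3' UTR frequency for all 64 triplets.  A ratio with zero 3' UTR frequency
#' is undefined and flagged.
#'
#' @param tl_seqs Character vector of transcript-leader sequences.
#' @param utr3_seqs Character vector of 3' UTR sequences.
#' @return Data frame with columns `triplet`, `tl_freq`, `utr3_freq`,
#'   `oe_ratio`, `undefined`.
#' @export
triplet_oe <- function(tl_seqs, utr3_seqs) {
  count3 <- function(seqs) {
    seqs <- seqs[nchar(seqs) >= 3]
    if (!length(seqs)) return(stats::setNames(rep(0, 64), Biostrings::mkAllStrings(c("A","C","G","T"), 3)))
    colSums(Biostrings::trinucleotideFrequency(
      Biostrings::DNAStringSet(toupper(seqs)), step = 1))
  }
  tl <- count3(tl_seqs); u3 <- count3(utr3_seqs)
  tl_f <- if (sum(tl) > 0) tl / sum(tl) else tl
  u3_f <- if (sum(u3) > 0) u3 / sum(u3) else u3
  oe <- ifelse(u3_f > 0, tl_f / u3_f, NA_real_)
  data.frame(triplet = names(tl), tl_freq = as.numeric(tl_f),
             utr3_freq = as.numeric(u3_f), oe_ratio = as.numeric(oe),
             undefined = u3_f == 0, row.names = NULL)
}

#' Transcript inclusion of a uORF
#'
#' The fraction of a gene's transcripts (TSS-usage weighted) that contain the
#' uORF: the summed usage of TSS isoforms whose start lies at or upstream of
#' the uORF start codon (strand-aware, transcript coordinates on the distal
#' leader).
#'
#' @param uorf_start_pos Transcript coordinate of the uORF start codon
#'   (distal-leader frame).
#' @param model A `transcript_model`.
#' @return List with `inclusion_fraction` in `[0, 1]` and `minority` flag
#'   (`inclusion < 0.5`).
#' @export
transcript_inclusion <- function(uorf_start_pos, model) {
  iso <- model$tl_isoforms
  tss_t <- to_transcript_coords(model, iso$tss)
  inc <- sum(iso$usage_fraction[tss_t <= uorf_start_pos])
  if (inc == 0) {
    warning("uORF at ", uorf_start_pos, " lies upstream of every TSS isoform of ",
            model$gene_id, " (candidates are enumerated on the distal leader)")
  }
  list(inclusion_fraction = inc, minority = inc < 0.5)
}

#' Translation efficiency of a region
#'
#' Ribosome-footprint density divided by RNA density over the same region
#' (both in reads per nucleotide or RPKM; the units cancel).
#'
#' @param ribo_density,rna_density Non-negative densities; `rna_density`
#'   must be positive.
#' @return Numeric TE.
#' @export
translation_efficiency <- function(ribo_density, rna_density) {
  stopifnot(all(rna_density > 0))
  ribo_density / rna_density
}

#' Pairwise rank-sum comparison of translation-efficiency groups
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups, with
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param te_values_by_group Named list of numeric TE vectors.
#' @return Data frame with `group1`, `group2`, `p_value`, `p_adjusted`.
#' @export
te_group_compare <- function(te_values_by_group) {
  stopifnot(length(te_values_by_group) >= 2L)
  nms <- names(te_values_by_group)
  pairs <- utils::combn(nms, 2)
  p <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(te_values_by_group[[pr[1]]],
                                        te_values_by_group[[pr[2]]],
                                        alternative = "two.sided")$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p,
             p_adjusted = stats::p.adjust(p, method = "BH"))
}

#' Eligible leader region for TIS metagene analysis
#'
#' Truncates a transcript leader `exclude_nt` nucleotides upstream of the
#' mORF start so protein interactions at the main-ORF initiation site are not
#' attributed to uORFs.
#'
#' @param leader_len Leader length in nucleotides.
#' @param exclude_nt Exclusion zone upstream of the mORF start (default 15).
#' @return Integer `c(start, end)` half-open region in transcript coordinates.
#' @export
leader_metagene_region <- function(leader_len, exclude_nt = 15L) {
  c(0L, max(0L, leader_len - exclude_nt))
}

#' RBP metagene around translation initiation sites
#'
#' Sums RNA-binding-protein site overlaps in 3-nt steps around each TIS
#' ("observed"), and estimates the expected profile by repeatedly resampling
#' TIS positions uniformly within each gene's eligible region and site
#' positions uniformly within the same transcript (default 1000 draws).
#' Only genes whose eligible region fully encloses a step's 3-nt window
#' contribute to that step, for both observed and sampled profiles.
#'
#' @param sites_by_gene Named list; per gene a data frame of site intervals
#'   (`start`, `end`, 0-based half-open, transcript coordinates).
#' @param tis_by_gene Named integer vector of TIS transcript coordinates.
#' @param region_by_gene Named list of eligible `c(start, end)` half-open
#'   regions (e.g. [leader_metagene_region()] output per gene).
#' @param half_window Half-width of the metagene in nucleotides (default 30).
#' @param n_samples Random draws for the background (default 1000).
#' @param seed Optional seed.
#' @return List with `steps` (offsets, 3-nt spacing), `observed`,
#'   `expected`, `lower`, `upper` (sampled 95% band), `n_samples`.
#' @export
rbp_metagene <- function(sites_by_gene, tis_by_gene, region_by_gene,
                         half_window = 30L, n_samples = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  steps <- seq(-half_window, half_window, by = 3L)
  genes <- names(tis_by_gene)
  profile_for <- function(tis, sites, region) {
    win_lo <- tis + steps
    win_hi <- win_lo + 3L                      # half-open 3-nt windows
    eligible <- win_lo >= region[1] & win_hi <= region[2]
    obs <- numeric(length(steps))
    if (nrow(sites) && any(eligible)) {
      for (k in which(eligible)) {
        obs[k] <- sum(sites$start < win_hi[k] & sites$end > win_lo[k])
      }
    }
    list(profile = obs, eligible = eligible)
  }
  observed <- numeric(length(steps))
  for (g in genes) {
    observed <- observed +
      profile_for(tis_by_gene[[g]], sites_by_gene[[g]], region_by_gene[[g]])$profile
  }
  samples <- matrix(0, n_samples, length(steps))
  for (s in seq_len(n_samples)) {
    prof <- numeric(length(steps))
    for (g in genes) {
      region <- region_by_gene[[g]]
      if (region[2] - region[1] < 1L) next
      tis_s <- sample(seq(region[1], region[2] - 1L), 1L)
      sites <- sites_by_gene[[g]]
      if (nrow(sites)) {
        w <- sites$end - sites$start
        max_start <- pmax(region[2] - w, region[1] + 1L)
        new_start <- vapply(max_start - region[1], function(m)
          region[1] + sample.int(m, 1L) - 1L, integer(1))
        sites <- data.frame(start = new_start, end = new_start + w)
      }
      prof <- prof + profile_for(tis_s, sites, region)$profile
    }
    samples[s, ] <- prof
  }
  list(steps = steps,
       observed = observed,
       expected = colMeans(samples),
       lower = apply(samples, 2, stats::quantile, probs = 0.025),
       upper = apply(samples, 2, stats::quantile, probs = 0.975),
       n_samples = n_samples)
}
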