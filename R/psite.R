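#' Read ribosome footprints (or RNA-seq reads) from a BAM file
#'
#' Returns a plain alignment table suitable for [assign_psites()] and
#' [rna_coverage()].  Unmapped, secondary, and supplementary records are
#' dropped; multi-mapped reads (MAPQ below `min_mapq`) are dropped because
#' uORFs are short and ambiguous placements are toxic.
#'
#' @param bam_path Path to an indexed or unindexed BAM file.
#' @param min_mapq Minimum mapping quality (default 10).
#' @return Data frame with columns `chrom`, `strand`, `start`, `end`
#'   (0-based half-open reference span) and `qwidth` (read length).
#' @export
read_footprints <- function(bam_path, min_mapq = 10L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_footprints() requires the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "strand", "pos", "qwidth", "cigar", "mapq"))
  b <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= min_mapq)
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
  data.frame(chrom = as.character(b$rname[keep]),
             strand = as.character(b$strand[keep]),
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + ref_width,
             qwidth = b$qwidth[keep])
}

#' Default P-site offset table
#'
#' Maps footprint read length to the P-site offset from the footprint's 5'
#' end.  Defaults: 28 nt -> 12, 29 nt -> 13, 30 nt -> 13.  Read lengths
#' absent from the table are dropped during assignment.
#'
#' @return Named integer vector (names = read lengths).
#' @export
default_offsets <- function() c(`28` = 12L, `29` = 13L, `30` = 13L)

#' Calibrate P-site offsets from annotated start codons
#'
#' For each read length, estimates the offset as the mode of (annotated mORF
#' start minus read 5' end) over reads whose 5' end lies within `max_offset`
#' nucleotides upstream of a start codon.  Data-driven alternative to
#' [default_offsets()].
#'
#' @param footprints Alignment table from [read_footprints()].
#' @param models Named list of `transcript_model` objects.
#' @param lengths Read lengths to calibrate (default 28:30).
#' @param max_offset Largest admissible offset (default 15; offsets outside
#'   `[10, 15]` are discarded).
#' @return Named integer vector like [default_offsets()].
#' @export
calibrate_offsets <- function(footprints, models, lengths = 28:30,
                              max_offset = 15L) {
  five_prime <- ifelse(footprints$strand == "+", footprints$start,
                       footprints$end - 1L)
  out <- integer(0)
  for (len in lengths) {
    sel <- footprints$qwidth == len
    if (!any(sel)) next
    deltas <- integer(0)
    for (m in models) {
      on_gene <- sel & footprints$chrom == m$chrom & footprints$strand == m$strand
      if (!any(on_gene)) next
      d <- if (m$strand == "+") m$morf_start - five_prime[on_gene]
           else five_prime[on_gene] - m$morf_start
      deltas <- c(deltas, d[d >= 10L & d <= max_offset])
    }
    if (length(deltas)) {
      tab <- table(deltas)
      out[as.character(len)] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  out
}

#' Assign ribosome P-sites to transcript coordinates
#'
#' Each footprint contributes +1 at its genomic 5' end plus the length-specific
#' offset (strand-aware: the 5' end of a minus-strand alignment is its
#' rightmost base and the offset runs leftwards).  P-sites are then mapped
#' into transcript coordinates (position 0 = distal TSS); reads whose P-site
#' falls outside the transcript, and reads whose length is absent from the
#' offset table, are dropped (counts recorded in attributes).
#'
#' @param footprints Alignment table from [read_footprints()] (one replicate).
#' @param offset_table Named integer vector, read length -> offset.
#' @param models Named list of `transcript_model` objects.
#' @return Named list (by gene) of integer P-site count vectors over
#'   transcript coordinates, with attributes `n_dropped_length` and
#'   `n_outside`.
#' @export
assign_psites <- function(footprints, offset_table = default_offsets(), models) {
  known <- footprints$qwidth %in% as.integer(names(offset_table))
  n_dropped <- sum(!known)
  fp <- footprints[known, , drop = FALSE]
  off <- offset_table[as.character(fp$qwidth)]
  psite <- ifelse(fp$strand == "+", fp$start + off, (fp$end - 1L) - off)
  tracks <- list()
  n_outside <- 0L
  for (m in models) {
    len <- transcript_length(m)
    track <- integer(len)
    sel <- fp$chrom == m$chrom & fp$strand == m$strand
    if (any(sel)) {
      t <- to_transcript_coords(m, psite[sel])
      inside <- t >= 0L & t < len
      n_outside <- n_outside + sum(!inside)
      if (any(inside)) {
        tb <- tabulate(t[inside] + 1L, nbins = len)
        track <- as.integer(tb)
      }
    }
    tracks[[m$gene_id]] <- track
  }
  if (n_dropped > 0) {
    message(n_dropped, " read(s) dropped: length absent from offset table")
  }
  attr(tracks, "n_dropped_length") <- n_dropped
  attr(tracks, "n_outside") <- n_outside
  tracks
}

#' RNA-seq coverage tracks in transcript coordinates
#'
#' Full-read coverage (every transcript position spanned by an alignment gets
#' +1), used for abundance features and translation efficiency only.
#'
#' @inheritParams assign_psites
#' @return Named list (by gene) of integer coverage vectors.
#' @export
rna_coverage <- function(footprints, models) {
  tracks <- list()
  for (m in models) {
    len <- transcript_length(m)
    track <- integer(len)
    sel <- footprints$chrom == m$chrom & footprints$strand == m$strand
    if (any(sel)) {
      t1 <- to_transcript_coords(m, footprints$start[sel])
      t2 <- to_transcript_coords(m, footprints$end[sel] - 1L)
      lo <- pmax(pmin(t1, t2), 0L)
      hi <- pmin(pmax(t1, t2), len - 1L)
      ok <- lo <= hi
      for (i in which(ok)) {
        track[(lo[i] + 1L):(hi[i] + 1L)] <- track[(lo[i] + 1L):(hi[i] + 1L)] + 1L
      }
    }
    tracks[[m$gene_id]] <- track
  }
  tracks
}

#' Fraction of P-sites in frame 0 of an ORF
#'
#' @param track Integer P-site vector in transcript coordinates.
#' @param orf_start Transcript coordinate of the ORF start codon's first
#'   nucleotide.
#' @param orf_len ORF length in nucleotides (multiple of 3, >= 3).
#' @return Fraction in `[0, 1]`, or `NA_real_` when the ORF has no P-sites.
#' @export
orf_frame_fraction <- function(track, orf_start, orf_len) {
  stopifnot(orf_len >= 3L, orf_len %% 3L == 0L,
            orf_start >= 0L, orf_start + orf_len <= length(track))
  idx <- (orf_start + 1L):(orf_start + orf_len)
  total <- sum(track[idx])
  if (total == 0) return(NA_real_)
  frame0 <- track[seq(orf_start + 1L, orf_start + orf_len, by = 3L)]
  sum(frame0) / total
}
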