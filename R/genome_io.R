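#' Read a genome FASTA
#'
#' Loads all records of a genome FASTA into a [Biostrings::DNAStringSet].
#' Bases are upper-cased and `U` is converted to `T`, so downstream code works
#' on a single DNA alphabet over `{A,C,G,T,N}` regardless of how the file was
#' written.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    stop("empty FASTA: ", fasta_path)
  }
  chr <- toupper(as.character(seqs))
  chr <- gsub("U", "T", chr, fixed = TRUE)
  out <- Biostrings::DNAStringSet(chr)
  # keep only the first whitespace-delimited token of each header
  names(out) <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  out
}

#' Construct a transcript model
#'
#' A transcript model holds a gene's strand, main-ORF (mORF) coordinates, its
#' transcript-leader isoforms (TSS positions with usage fractions), its
#' polyadenylation sites, and its 3' UTR interval.  All coordinates are
#' 0-based genomic positions; intervals are half-open.  `morf_start` is the
#' first nucleotide of the start codon and `morf_stop` the last nucleotide of
#' the stop codon, so on the minus strand `morf_start > morf_stop`.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param morf_start,morf_stop Genomic positions (0-based) of the mORF start
#'   codon's first nucleotide and stop codon's last nucleotide.
#' @param tss Integer vector of TSS positions (0-based).
#' @param tss_usage Non-negative usage weights per TSS; renormalized to sum
#'   to 1.
#' @param pa Integer vector of polyadenylation-site positions.
#' @param pa_usage Usage weights per pA site; renormalized.
#' @param utr3 Optional genomic interval `c(start, end)` (0-based half-open)
#'   of the 3' UTR.
#' @return An object of class `"transcript_model"`.
#' @export
transcript_model <- function(gene_id, chrom, strand, morf_start, morf_stop,
                             tss, tss_usage = rep(1, length(tss)),
                             pa = integer(0), pa_usage = rep(1, length(pa)),
                             utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"), length(tss) >= 1L,
            length(tss_usage) == length(tss), all(tss_usage >= 0),
            sum(tss_usage) > 0)
  upstream_ok <- if (strand == "+") all(tss < morf_start) else all(tss > morf_start)
  if (!upstream_ok) {
    stop("gene ", gene_id, ": every TSS must be strand-aware upstream of the mORF start")
  }
  if (length(pa)) {
    down_ok <- if (strand == "+") all(pa > morf_stop) else all(pa < morf_stop)
    if (!down_ok) stop("gene ", gene_id, ": every pA must be downstream of the mORF stop")
    pa_usage <- pa_usage / sum(pa_usage)
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    morf_start = as.integer(morf_start), morf_stop = as.integer(morf_stop),
    tl_isoforms = data.frame(tss = as.integer(tss),
                             usage_fraction = tss_usage / sum(tss_usage)),
    pa_sites = data.frame(pa = as.integer(pa),
                          usage_fraction = if (length(pa)) pa_usage else numeric(0)),
    utr3_interval = utr3
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model ", x$gene_id, " (", x$chrom, x$strand, ")\n",
      "  mORF: ", x$morf_start, "..", x$morf_stop,
      "  TSS isoforms: ", nrow(x$tl_isoforms),
      "  pA sites: ", nrow(x$pa_sites), "\n", sep = "")
  invisible(x)
}

## -- strand-aware geometry helpers -----------------------------------------

#' Most distal TSS of a model (strand-aware most-upstream)
#' @param model A `transcript_model`.
#' @return Genomic position (0-based) of the most upstream TSS.
#' @export
distal_tss <- function(model) {
  if (model$strand == "+") min(model$tl_isoforms$tss) else max(model$tl_isoforms$tss)
}

#' Leader length from a given TSS to the mORF start
#' @param model A `transcript_model`.
#' @param tss A TSS genomic position; defaults to the distal TSS.
#' @return Leader length in nucleotides (0 when the TSS abuts the start codon).
#' @export
leader_length <- function(model, tss = distal_tss(model)) {
  if (model$strand == "+") model$morf_start - tss else tss - model$morf_start
}

#' mORF length in nucleotides
#' @param model A `transcript_model`.
#' @export
morf_length <- function(model) abs(model$morf_stop - model$morf_start) + 1L

#' Transcript length (distal leader + mORF) in nucleotides
#' @param model A `transcript_model`.
#' @export
transcript_length <- function(model) leader_length(model) + morf_length(model)

#' Map genomic positions into transcript coordinates
#'
#' Transcript position 0 is the most distal TSS; coordinates increase 5' to 3'
#' along the transcript regardless of genomic strand.
#'
#' @param model A `transcript_model`.
#' @param gpos Integer vector of 0-based genomic positions.
#' @return Integer vector of transcript coordinates (may be negative or beyond
#'   the transcript end; callers filter to `[0, transcript_length)`).
#' @export
to_transcript_coords <- function(model, gpos) {
  d <- distal_tss(model)
  if (model$strand == "+") as.integer(gpos - d) else as.integer(d - gpos)
}

#' Extract the transcript-leader sequence
#'
#' Returns the leader 5' to 3' in transcript orientation, from the chosen TSS
#' to the nucleotide before the mORF start codon; minus-strand leaders are
#' reverse-complemented.
#'
#' @param model A `transcript_model`.
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param tss_choice One of the model's TSS positions, or `"distal"` for the
#'   most upstream TSS.
#' @return A character scalar (empty when the TSS abuts the start codon).
#' @export
tl_sequence <- function(model, genome, tss_choice = "distal") {
  tss <- if (identical(tss_choice, "distal")) distal_tss(model) else {
    if (!tss_choice %in% model$tl_isoforms$tss) {
      stop("tss_choice ", tss_choice, " is not a TSS of gene ", model$gene_id)
    }
    as.integer(tss_choice)
  }
  n <- leader_length(model, tss)
  if (n == 0L) return("")
  chrom_seq <- genome[[model$chrom]]
  if (model$strand == "+") {
    as.character(Biostrings::subseq(chrom_seq, start = tss + 1L, width = n))
  } else {
    g <- Biostrings::subseq(chrom_seq, start = model$morf_start + 2L, width = n)
    as.character(Biostrings::reverseComplement(g))
  }
}

#' Transcript sequence (distal leader + mORF), transcript orientation
#' @inheritParams tl_sequence
#' @export
transcript_sequence <- function(model, genome) {
  chrom_seq <- genome[[model$chrom]]
  if (model$strand == "+") {
    as.character(Biostrings::subseq(chrom_seq, start = distal_tss(model) + 1L,
                                    end = model$morf_stop + 1L))
  } else {
    g <- Biostrings::subseq(chrom_seq, start = model$morf_stop + 1L,
                            end = distal_tss(model) + 1L)
    as.character(Biostrings::reverseComplement(g))
  }
}

## -- annotation I/O ---------------------------------------------------------

#' Read transcript models from GFF3 + TSS/pA BED files
#'
#' Genes and CDS records come from the GFF3 (1-based inclusive, converted to
#' the package's 0-based half-open convention at this boundary); TSS and pA
#' cluster positions and usage counts come from BED6 files whose `name` column
#' carries the gene id and whose `score` column carries the usage count.
#' Usage fractions are renormalized per gene and per end.  Genes lacking a TSS
#' or a pA record, genes with multi-exon structure (annotated introns), and
#' TSS records downstream of the mORF start are dropped with a warning.
#'
#' @param gff3_path GFF3 with `gene` and `CDS` features (gene `ID` attribute).
#' @param tl_bed_path BED6 of TSS clusters.
#' @param pa_bed_path BED6 of pA clusters.
#' @return A named list of `transcript_model` objects.
#' @export
read_transcript_models <- function(gff3_path, tl_bed_path, pa_bed_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_transcript_models() requires the rtracklayer package")
  }
  gff <- rtracklayer::import(gff3_path)
  bed_tl <- rtracklayer::import(tl_bed_path)
  bed_pa <- rtracklayer::import(pa_bed_path)

  genes <- gff[gff$type == "gene"]
  cds <- gff[gff$type == "CDS"]
  cds_parent <- sub("^.*?:", "", as.character(
    vapply(as.list(cds$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           "")))
  cds_parent <- sub("_mRNA$|_cds$", "", cds_parent)

  models <- list()
  dropped <- character(0)
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- g$ID
    strand <- as.character(BiocGenerics::strand(g))
    gcds <- cds[cds_parent == gid | (!is.na(cds$ID) & cds$ID == gid)]
    if (length(gcds) == 0L) { dropped <- c(dropped, gid); next }
    if (length(gcds) > 1L) {
      warning("gene ", gid, " has multi-exon CDS (annotated introns); excluded")
      dropped <- c(dropped, gid); next
    }
    # GFF3 1-based inclusive -> 0-based
    lo <- BiocGenerics::start(gcds) - 1L
    hi <- BiocGenerics::end(gcds) - 1L
    morf_start <- if (strand == "+") lo else hi
    morf_stop <- if (strand == "+") hi else lo

    tl_rows <- bed_tl[bed_tl$name == gid]
    pa_rows <- bed_pa[bed_pa$name == gid]
    if (length(tl_rows) == 0L || length(pa_rows) == 0L) {
      dropped <- c(dropped, gid); next
    }
    tss <- BiocGenerics::start(tl_rows) - 1L
    ok <- if (strand == "+") tss < morf_start else tss > morf_start
    if (any(!ok)) {
      warning("gene ", gid, ": ", sum(!ok),
              " TSS record(s) downstream of the mORF start rejected")
      tl_rows <- tl_rows[ok]; tss <- tss[ok]
    }
    if (length(tss) == 0L) { dropped <- c(dropped, gid); next }
    pa <- BiocGenerics::start(pa_rows) - 1L
    utr3 <- if (strand == "+") c(morf_stop + 1L, max(pa) + 1L)
            else c(min(pa), morf_stop)
    models[[gid]] <- transcript_model(
      gene_id = gid, chrom = as.character(GenomeInfoDb::seqnames(g)),
      strand = strand, morf_start = morf_start, morf_stop = morf_stop,
      tss = tss, tss_usage = tl_rows$score,
      pa = pa, pa_usage = pa_rows$score, utr3 = utr3)
  }
  if (length(dropped)) {
    message(length(dropped), " gene(s) excluded (no TSS/pA, introns, or no CDS): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  models
}

#' Write transcript models to GFF3 + TSS/pA BED files
#'
#' Inverse of [read_transcript_models()]: the written files re-read to the
#' same coordinates.  BED scores hold usage fractions scaled to parts per
#' thousand (rounded).
#'
#' @param models Named list of `transcript_model` objects.
#' @param gff3_path,tl_bed_path,pa_bed_path Output paths.
#' @export
write_transcript_models <- function(models, gff3_path, tl_bed_path, pa_bed_path) {
  gff_lines <- c("##gff-version 3")
  tl_lines <- character(0)
  pa_lines <- character(0)
  for (m in models) {
    lo <- min(m$morf_start, m$morf_stop); hi <- max(m$morf_start, m$morf_stop)
    gff_lines <- c(gff_lines,
      paste(m$chrom, "uorfseqr", "gene", lo + 1L, hi + 1L, ".", m$strand, ".",
            paste0("ID=", m$gene_id), sep = "\t"),
      paste(m$chrom, "uorfseqr", "CDS", lo + 1L, hi + 1L, ".", m$strand, "0",
            paste0("ID=", m$gene_id, "_cds;Parent=", m$gene_id), sep = "\t"))
    tl_lines <- c(tl_lines, paste(m$chrom, m$tl_isoforms$tss,
      m$tl_isoforms$tss + 1L, m$gene_id,
      round(1000 * m$tl_isoforms$usage_fraction), m$strand, sep = "\t"))
    if (nrow(m$pa_sites)) {
      pa_lines <- c(pa_lines, paste(m$chrom, m$pa_sites$pa, m$pa_sites$pa + 1L,
        m$gene_id, round(1000 * m$pa_sites$usage_fraction), m$strand, sep = "\t"))
    }
  }
  writeLines(gff_lines, gff3_path)
  writeLines(tl_lines, tl_bed_path)
  writeLines(pa_lines, pa_bed_path)
  invisible(NULL)
}
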