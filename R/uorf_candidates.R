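#' Start and stop codon sets
#'
#' The uORF start-codon universe is AUG plus the seven near-cognate codons
#' (single-nucleotide variants of AUG) that support initiation; AGG and AAG
#' are excluded as non-initiating.  Reported here in DNA form.
#'
#' @return Character vector of codons.
#' @export
uorf_start_codons <- function() c("ATG", "TTG", "CTG", "GTG", "ACG", "ATA", "ATT", "ATC")

#' @rdname uorf_start_codons
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' Enumerate candidate uORFs in a transcript leader
#'
#' Scans every position of the leader (taken from the most distal TSS) for an
#' AUG or near-cognate start codon and pairs it with the first in-frame stop
#' codon.  Stops are sought in `morf_context_seq` (leader followed by mORF)
#' so that candidates whose stop lies at or beyond the mORF start are still
#' enumerated; these carry `overlaps_morf = TRUE`.  Starts without any
#' in-frame stop in the context (would-be N-terminal extensions) are not
#' candidates.
#'
#' @param leader_seq Leader DNA sequence (transcript orientation, 5' to 3').
#' @param morf_context_seq Leader plus mORF sequence; must begin with
#'   `leader_seq`.  Defaults to the leader alone.
#' @param gene_id Optional gene id carried into the output.
#' @return Data frame with columns `gene_id`, `start_pos`, `stop_pos`
#'   (transcript coordinates of the start codon's first and the stop codon's
#'   last nucleotide), `start_codon`, `length_nt`, `overlaps_morf`.
#' @examples
#' enumerate_candidates("ATGAAATAA")   # one AUG uORF of 9 nt
#' @export
enumerate_candidates <- function(leader_seq, morf_context_seq = leader_seq,
                                 gene_id = NA_character_) {
  empty <- data.frame(gene_id = character(0), start_pos = integer(0),
                      stop_pos = integer(0), start_codon = character(0),
                      length_nt = integer(0), overlaps_morf = logical(0))
  ll <- nchar(leader_seq)
  if (ll < 3L) return(empty)
  if (substr(morf_context_seq, 1L, ll) != leader_seq) {
    stop("morf_context_seq must begin with leader_seq")
  }
  ctx <- toupper(morf_context_seq)
  L <- nchar(ctx)
  codons <- substring(ctx, 1:(L - 2L), 3:L)       # codon starting at 0-based p = i-1
  is_start <- codons %in% uorf_start_codons()
  is_stop <- codons %in% stop_codons()

  # first in-frame stop at or after each position, per frame (0-based pos p)
  next_stop <- rep(NA_integer_, L - 2L)
  for (i in seq(L - 2L, 1L)) {
    if (is_stop[i]) next_stop[i] <- i - 1L
    else if (i + 3L <= L - 2L) next_stop[i] <- next_stop[i + 3L]
  }

  start_idx <- which(is_start[seq_len(min(ll - 2L, L - 2L))])
  if (!length(start_idx)) return(empty)
  rows <- lapply(start_idx, function(i) {
    if (i + 3L > L - 2L) return(NULL)
    s <- next_stop[i + 3L]               # first stop strictly downstream, in frame
    if (is.na(s)) return(NULL)
    start_pos <- i - 1L
    stop_pos <- s + 2L
    data.frame(gene_id = gene_id, start_pos = start_pos, stop_pos = stop_pos,
               start_codon = codons[i], length_nt = stop_pos - start_pos + 1L,
               overlaps_morf = stop_pos >= ll)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve overlapping and nested candidate uORFs
#'
#' Greedy selection by descending score: a candidate is retained iff its
#' `[start_pos, stop_pos]` interval does not overlap any already-retained
#' candidate of the same gene.  Ties on score prefer the longer candidate,
#' then the more upstream one.
#'
#' @param scored_candidates Candidate data frame with a `score` column (and
#'   `gene_id`, `start_pos`, `stop_pos`, `length_nt`).
#' @return The retained subset, original row order within each gene by
#'   position.
#' @export
resolve_overlaps <- function(scored_candidates) {
  x <- scored_candidates
  if (nrow(x) == 0L) return(x)
  stopifnot("score" %in% names(x))
  keep <- logical(nrow(x))
  ord <- order(-x$score, -x$length_nt, x$start_pos)
  for (g in unique(x$gene_id)) {
    gi <- ord[x$gene_id[ord] %in% g]
    ret_start <- integer(0); ret_stop <- integer(0)
    for (i in gi) {
      s <- x$start_pos[i]; e <- x$stop_pos[i]
      if (!any(s <= ret_stop & e >= ret_start)) {
        keep[i] <- TRUE
        ret_start <- c(ret_start, s); ret_stop <- c(ret_stop, e)
      }
    }
  }
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$gene_id, out$start_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
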