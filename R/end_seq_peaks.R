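#' Construct an end-seq pileup
#'
#' Sparse container for single-nucleotide read-end counts on one chromosome
#' and strand (5' ends for TL-seq, 3' ends for pA-seq).
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param pos Integer vector of 0-based genomic positions with nonzero counts.
#' @param count Positive integer counts, same length as `pos`.
#' @return An object of class `"end_pileup"`.
#' @export
end_pileup <- function(chrom, strand, pos, count) {
  stopifnot(strand %in% c("+", "-"), length(pos) == length(count),
            all(count >= 0))
  keep <- count > 0
  o <- order(pos[keep])
  structure(list(chrom = chrom, strand = strand,
                 pos = as.integer(pos[keep])[o],
                 count = as.integer(count[keep])[o]),
            class = "end_pileup")
}

#' @export
print.end_pileup <- function(x, ...) {
  cat("End pileup ", x$chrom, x$strand, ": ", length(x$pos),
      " covered positions, ", sum(x$count), " read ends\n", sep = "")
  invisible(x)
}

#' Read a bedGraph track into an end pileup
#'
#' @param path bedGraph file (chrom, start, end, value), 0-based half-open.
#' @param chrom Chromosome to keep.
#' @param strand Strand label to attach (bedGraph itself is unstranded; the
#'   two strands are conventionally shipped as separate files).
#' @return An `end_pileup`.
#' @export
read_end_bedgraph <- function(path, chrom, strand = "+") {
  bg <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"))
  bg <- bg[bg$chrom == chrom & bg$value > 0, , drop = FALSE]
  pos <- unlist(Map(function(s, e) s:(e - 1L), bg$start, bg$end), use.names = FALSE)
  cnt <- rep(bg$value, bg$end - bg$start)
  end_pileup(chrom, strand, pos, cnt)
}

#' Write an end pileup as bedGraph
#' @param pileup An `end_pileup`.
#' @param path Output path.
#' @export
write_end_bedgraph <- function(pileup, path) {
  writeLines(paste(pileup$chrom, pileup$pos, pileup$pos + 1L, pileup$count,
                   sep = "\t"), path)
  invisible(NULL)
}

#' Call significant TSS/pA peaks from an end pileup
#'
#' Fits the trend-filtered Poisson background ([fit_poisson_trend()]) per
#' window, computes a per-position upper-tail Poisson p-value for every
#' covered position, applies Benjamini-Hochberg across all tested positions,
#' and reports positions with q-value at or below `beta`.  Zero-count
#' positions are never tested, so the FDR universe is the covered positions
#' inside the supplied windows.
#'
#' @param pileup An `end_pileup`.
#' @param beta FDR level; default 0.001.  `beta <= 0` returns an empty set.
#' @param windows Optional data frame with columns `start`, `end` (0-based
#'   half-open) restricting the search space, e.g. 1 kb gene flanks.
#'   Default: the covered range, processed in genome tiles of at most
#'   `tile_nt` so each tile gets its own local background.
#' @param tile_nt Maximum default window length (default 2000).
#' @param lambda_penalty Passed to [fit_poisson_trend()] (`NULL` = per-window
#'   automatic choice).
#' @return A data frame (class `"peak_set"`) with columns `position`,
#'   `count`, `background_rate`, `p_value`, `q_value`, sorted by position;
#'   the penalty used per window is recorded in `attr(, "lambda")`.
#' @export
call_end_peaks <- function(pileup, beta = 0.001, windows = NULL,
                           lambda_penalty = NULL, tile_nt = 2000L) {
  stopifnot(inherits(pileup, "end_pileup"), beta < 1)
  empty <- data.frame(position = integer(0), count = integer(0),
                      background_rate = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  if (length(pileup$pos) == 0L || beta <= 0) return(empty)
  if (is.null(windows)) {
    lo <- min(pileup$pos); hi <- max(pileup$pos) + 1L
    starts <- seq(lo, hi - 1L, by = tile_nt)
    windows <- data.frame(start = starts, end = pmin(starts + tile_nt, hi))
  }
  res <- list(); lambdas <- numeric(0)
  for (w in seq_len(nrow(windows))) {
    lo <- windows$start[w]; hi <- windows$end[w]
    in_w <- pileup$pos >= lo & pileup$pos < hi
    if (!any(in_w)) next
    counts <- integer(hi - lo)
    counts[pileup$pos[in_w] - lo + 1L] <- pileup$count[in_w]
    if (length(counts) < 3L) next
    fit <- fit_poisson_trend(counts, lambda_penalty = lambda_penalty)
    lambdas <- c(lambdas, fit$lambda)
    covered <- which(counts > 0)
    bg <- pmax(fit$background_rate[covered], 1e-8)
    p <- stats::ppois(counts[covered] - 1, bg, lower.tail = FALSE)
    res[[length(res) + 1L]] <- data.frame(
      position = lo + covered - 1L, count = counts[covered],
      background_rate = fit$background_rate[covered], p_value = p)
  }
  if (!length(res)) return(empty)
  tab <- do.call(rbind, res)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  out <- tab[tab$q_value <= beta, , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- lambdas
  attr(out, "n_tested") <- nrow(tab)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Cluster called peaks into TSS/pA site clusters
#'
#' Single-linkage clustering along the coordinate: consecutive peaks at most
#' `window_nt` apart join one cluster.  The representative position is the
#' member with the highest count (ties broken towards the strand-aware
#' upstream member), and usage fractions are cluster totals normalized over
#' all clusters of the gene.
#'
#' @param peaks A `peak_set` (or data frame with `position` and `count`)
#'   belonging to one gene.
#' @param window_nt Linkage window in nucleotides (default 25).
#' @param strand `"+"` or `"-"`, for the upstream tie-break.
#' @return Data frame with columns `representative`, `start`, `end`
#'   (half-open member span), `n_members`, `total_count`, `usage_fraction`.
#' @export
cluster_sites <- function(peaks, window_nt = 25L, strand = "+") {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(data.frame(representative = integer(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      total_count = integer(0), usage_fraction = numeric(0)))
  }
  o <- order(peaks$position)
  pos <- peaks$position[o]; cnt <- peaks$count[o]
  cl <- cumsum(c(1L, as.integer(diff(pos) > window_nt)))
  reps <- integer(max(cl)); starts <- integer(max(cl)); ends <- integer(max(cl))
  nm <- integer(max(cl)); tot <- numeric(max(cl))
  for (k in seq_len(max(cl))) {
    idx <- which(cl == k)
    p <- pos[idx]; cc <- cnt[idx]
    best <- which(cc == max(cc))
    rep_pos <- if (strand == "+") min(p[best]) else max(p[best])
    reps[k] <- rep_pos; starts[k] <- min(p); ends[k] <- max(p) + 1L
    nm[k] <- length(idx); tot[k] <- sum(cc)
  }
  data.frame(representative = reps, start = starts, end = ends,
             n_members = nm, total_count = tot,
             usage_fraction = tot / sum(tot))
}

#' TSS-usage-weighted average transcript-leader length
#'
#' @param model A `transcript_model` with at least one TSS isoform.
#' @return The usage-weighted mean leader length in nucleotides; always
#'   between the shortest and longest member leader.
#' @export
weighted_avg_tl_length <- function(model) {
  iso <- model$tl_isoforms
  lens <- vapply(iso$tss, function(t) leader_length(model, t), numeric(1))
  sum(iso$usage_fraction * lens)
}

#' Coefficient of variation of leader lengths across species
#'
#' Population standard deviation divided by the mean.  Genes with CV below
#' `threshold` (the lowest-decile cutoff 0.06) are classified as having the
#' most conserved leader lengths by [cv_conserved_flag()].
#'
#' @param lengths Numeric vector of leader lengths, one per species (>= 2).
#' @return The CV, or `NA_real_` when the mean is 0.
#' @export
tl_length_cv <- function(lengths) {
  stopifnot(length(lengths) >= 2L)
  m <- mean(lengths)
  if (m == 0) return(NA_real_)
  sqrt(mean((lengths - m)^2)) / m
}

#' @rdname tl_length_cv
#' @param cv Numeric vector of CV values.
#' @param threshold Conservation cutoff (default 0.06).
#' @export
cv_conserved_flag <- function(cv, threshold = 0.06) {
  !is.na(cv) & cv < threshold
}
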