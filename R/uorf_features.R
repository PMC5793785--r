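#' Names of the 18 candidate-uORF features
#'
#' The feature set covers ribosome-occupancy evidence (densities, start-codon
#' peak, 3-nt periodicity, codon coverage, enrichment over leader and mORF
#' backgrounds, initiation and termination boundary signals, RNA abundance
#' and translation efficiency) and leader geometry (length, distances to TSS
#' and mORF, relative position).  The start-codon identity is deliberately
#' not a feature, to avoid biasing the model towards AUG over near-cognate
#' starts.  All log-scale features use `log2(x + 1)`.
#'
#' @return Character vector of 18 feature names.
#' @export
uorf_feature_names <- function() c(
  "uorf_density_log",        # 1  P-site density per nt over the uORF (log2(x+1))
  "start_count_log",         # 2  P-sites on the start codon (log2(x+1))
  "inframe_fraction",        # 3  fraction of uORF P-sites in frame 0 (0 if none)
  "codon_coverage",          # 4  fraction of uORF codons with >= 1 P-site
  "leader_enrichment_log",   # 5  uORF density / leader background density
  "morf_ratio_log",          # 6  uORF density / mORF density
  "start_peak_ratio",        # 7  first-codon density / rest-of-uORF density
  "upstream6_log",           # 8  P-sites in the 6 nt upstream of the start
  "downstream6_log",         # 9  P-sites in the 6 nt downstream of the stop
  "stop_dropoff_log",        # 10 drop-off across the stop codon
  "rna_coverage_log",        # 11 mean RNA-seq coverage over the uORF
  "ribo_rna_ratio_log",      # 12 Ribo/RNA ratio over the uORF
  "length_codons",           # 13 uORF length in codons
  "tss_distance",            # 14 distal TSS -> start distance (nt)
  "morf_distance",           # 15 stop -> mORF start distance (nt)
  "relative_position",       # 16 start position / leader length
  "leader_length_log",       # 17 leader length (log2(x+1))
  "has_coverage"             # 18 indicator: any P-site on the uORF
)

# sum of a track over 0-based transcript interval [lo, hi], clipped
.track_sum <- function(track, lo, hi) {
  lo <- max(lo, 0L); hi <- min(hi, length(track) - 1L)
  if (lo > hi) return(0)
  sum(track[(lo + 1L):(hi + 1L)])
}

#' Compute the 18-feature matrix for a gene's candidates
#'
#' Deterministic given the pooled P-site track, RNA coverage track, and
#' leader geometry.  Background densities of zero are imputed to one count
#' over the corresponding region so ratio features stay finite; frame
#' fraction with zero reads is imputed to 0, paired with the `has_coverage`
#' indicator.
#'
#' @param candidates Candidate data frame from [enumerate_candidates()] (one
#'   gene, transcript coordinates on the distal leader).
#' @param pooled_psites Integer vector: replicate-summed P-site track over
#'   transcript coordinates.
#' @param rna Integer vector: RNA-seq coverage track, same length.
#' @param leader_len Leader length in nucleotides (mORF starts at this
#'   transcript coordinate).
#' @return Numeric matrix, `nrow(candidates)` x 18, columns named as
#'   [uorf_feature_names()].
#' @export
compute_features <- function(candidates, pooled_psites, rna, leader_len) {
  txlen <- length(pooled_psites)
  stopifnot(length(rna) == txlen, leader_len <= txlen)
  nm <- uorf_feature_names()
  X <- matrix(0, nrow(candidates), length(nm), dimnames = list(NULL, nm))
  if (nrow(candidates) == 0L) return(X)
  if (any(candidates$stop_pos >= txlen | candidates$start_pos < 0L)) {
    stop("candidate outside track bounds")
  }
  morf_len <- max(txlen - leader_len, 1L)
  morf_count <- .track_sum(pooled_psites, leader_len, txlen - 1L)
  d_morf <- if (morf_count > 0) morf_count / morf_len else 1 / morf_len
  leader_total <- .track_sum(pooled_psites, 0L, leader_len - 1L)

  for (i in seq_len(nrow(candidates))) {
    s <- candidates$start_pos[i]; e <- candidates$stop_pos[i]
    len <- e - s + 1L
    n_u <- .track_sum(pooled_psites, s, e)
    d_u <- n_u / len
    # leader background excludes the uORF itself
    in_leader_hi <- min(e, leader_len - 1L)
    bg_count <- leader_total - .track_sum(pooled_psites, s, in_leader_hi)
    bg_len <- leader_len - (in_leader_hi - min(s, leader_len - 1L) + 1L)
    d_bg <- if (bg_len > 0 && bg_count > 0) bg_count / bg_len
            else 1 / max(leader_len, 1L)
    idx <- (s + 1L):(e + 1L)
    seg <- pooled_psites[idx]
    frame0 <- sum(seg[seq(1L, len, by = 3L)])
    codon_counts <- colSums(matrix(seg, nrow = 3L))
    c1 <- codon_counts[1L]
    rest_len <- len - 3L
    d_rest <- if (rest_len > 0) {
      r <- (n_u - c1) / rest_len
      if (r > 0) r else 1 / rest_len
    } else 1 / 3
    last6 <- .track_sum(pooled_psites, e - 5L, e)
    down6 <- .track_sum(pooled_psites, e + 1L, e + 6L)
    up6 <- .track_sum(pooled_psites, s - 6L, s - 1L)
    rna_u <- .track_sum(rna, s, e)

    X[i, ] <- c(
      log2(d_u + 1),
      log2(.track_sum(pooled_psites, s, s + 2L) + 1),
      if (n_u > 0) frame0 / n_u else 0,
      mean(codon_counts > 0),
      log2(d_u / d_bg + 1),
      log2(d_u / d_morf + 1),
      (c1 / 3) / d_rest,
      log2(up6 + 1),
      log2(down6 + 1),
      log2((last6 + 1) / (down6 + 1)),
      log2(rna_u / len + 1),
      log2((n_u + 1) / (rna_u + 1)),
      len / 3,
      s,
      leader_len - e - 1L,
      if (leader_len > 0) s / leader_len else 0,
      log2(leader_len + 1),
      as.numeric(n_u > 0)
    )
  }
  X
}

#' Default parameters of the per-replicate heuristic detector
#' @return Named list: `min_start_count`, `min_total`, `min_inframe_frac`.
#' @export
default_detect_params <- function() {
  list(min_start_count = 1L, min_total = 4L, min_inframe_frac = 0.5)
}

#' Heuristic uORF detection in a single replicate
#'
#' A candidate is detected in a replicate iff the P-site count on its start
#' codon, its total P-site count, and its in-frame fraction all reach the
#' configured thresholds.  The resulting per-replicate labels form the
#' regression target (fraction of replicates detected).
#'
#' @param candidates Candidate data frame (one gene).
#' @param replicate_track Integer P-site vector for one replicate.
#' @param params See [default_detect_params()].
#' @return Logical vector, one element per candidate.
#' @export
detect_in_replicate <- function(candidates, replicate_track,
                                params = default_detect_params()) {
  vapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates$start_pos[i]; e <- candidates$stop_pos[i]
    total <- .track_sum(replicate_track, s, e)
    if (total < params$min_total) return(FALSE)
    if (.track_sum(replicate_track, s, s + 2L) < params$min_start_count) return(FALSE)
    frame0 <- sum(replicate_track[seq(s + 1L, e + 1L, by = 3L)])
    frame0 / total >= params$min_inframe_frac
  }, logical(1))
}

#' Fraction of replicates in which each candidate is detected
#'
#' @param candidates Candidate data frame (one gene).
#' @param replicate_tracks List of per-replicate P-site vectors.
#' @inheritParams detect_in_replicate
#' @return Numeric vector in `{0, 1/n, ..., 1}`.
#' @export
detection_fraction <- function(candidates, replicate_tracks,
                               params = default_detect_params()) {
  if (nrow(candidates) == 0L) return(numeric(0))
  labs <- vapply(replicate_tracks, detect_in_replicate,
                 logical(nrow(candidates)), candidates = candidates,
                 params = params)
  if (nrow(candidates) == 1L) labs <- matrix(labs, nrow = 1L)
  rowMeans(labs)
}
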