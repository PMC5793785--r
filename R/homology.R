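#' HOXD70 nucleotide substitution matrix
#'
#' The symmetric 4x4 substitution scores used for cross-species
#' transcript-leader alignment (match rewards 91-100, transition/transversion
#' penalties), with the conventional gap-open 400 and gap-extend 30
#' penalties.
#'
#' @return Numeric 4x4 matrix with dimnames A, C, G, T.
#' @export
hoxd70_matrix <- function() {
  m <- matrix(c(
     91, -114,  -31, -123,
   -114,  100, -125,  -31,
    -31, -125,  100, -114,
   -123,  -31, -114,   91), 4, 4, byrow = TRUE,
   dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m
}

#' Locally align a uORF sequence into another species' transcript leader
#'
#' Smith-Waterman local alignment under the HOXD70 matrix.  The mapped
#' interval is the leader region covered by the aligned uORF residues
#' (0-based half-open leader coordinates).  A Z-score is computed against
#' `n_shuffles` mononucleotide shuffles of the uORF aligned to the same
#' leader; it is used to break ties between alternative placements.
#'
#' @param uorf_seq uORF DNA sequence (non-empty).
#' @param other_tl_seq Homologous-gene transcript-leader sequence (non-empty).
#' @param matrix Substitution matrix (default [hoxd70_matrix()]).
#' @param gap_open,gap_ext Gap penalties (defaults 400 / 30).
#' @param n_shuffles Shuffle draws for the Z-score (default 100); `0` skips
#'   the Z-score.
#' @param seed Optional seed for the shuffles.
#' @return List with `score`, `mapped_start`, `mapped_end` (half-open),
#'   `z_score` (`NA` when the shuffle scores have zero spread), and the
#'   `alignment` object.
#' @export
align_uorf_to_tl <- function(uorf_seq, other_tl_seq, matrix = hoxd70_matrix(),
                             gap_open = 400, gap_ext = 30,
                             n_shuffles = 100L, seed = NULL) {
  stopifnot(nchar(uorf_seq) > 0, nchar(other_tl_seq) > 0)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(uorf_seq),
    subject = Biostrings::DNAString(other_tl_seq),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_ext)
  sc <- Biostrings::score(aln)
  subj <- Biostrings::subject(aln)
  mapped_start <- Biostrings::start(subj) - 1L
  mapped_end <- Biostrings::end(subj)           # half-open
  z <- NA_real_
  if (n_shuffles > 0L) {
    if (!is.null(seed)) set.seed(seed)
    chars <- strsplit(uorf_seq, "")[[1]]
    shuf <- vapply(seq_len(n_shuffles),
                   function(i) paste(sample(chars), collapse = ""), "")
    null_sc <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(shuf),
      subject = Biostrings::DNAString(other_tl_seq),
      type = "local", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
    s <- stats::sd(null_sc)
    if (!is.na(s) && s > 0) z <- (sc - mean(null_sc)) / s
  }
  list(score = sc, mapped_start = mapped_start, mapped_end = mapped_end,
       z_score = z, alignment = aln)
}

#' Jaccard index of two half-open intervals
#'
#' @param interval_a,interval_b Integer vectors `c(start, end)`, 0-based
#'   half-open.
#' @return `|intersection| / |union|` over nucleotide positions; 0 when
#'   disjoint or both empty.
#' @export
jaccard_index <- function(interval_a, interval_b) {
  inter <- max(0L, min(interval_a[2], interval_b[2]) -
                   max(interval_a[1], interval_b[1]))
  union <- (interval_a[2] - interval_a[1]) + (interval_b[2] - interval_b[1]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Sequence homologs between two species' uORF calls
#'
#' For each call in species A, aligns its sequence into the homologous gene's
#' leader in species B ([align_uorf_to_tl()]) and pairs it with the B call
#' whose interval overlaps the mapped interval with the greatest Jaccard
#' index, provided it reaches `threshold` (default 0.6); alignment-score
#' Z-scores break ties.
#'
#' @param calls_a,calls_b Call data frames (columns of
#'   [enumerate_candidates()] at minimum) for the two species.
#' @param gene_pairs Data frame with columns `gene_a`, `gene_b` mapping
#'   homologous genes.
#' @param tl_a,tl_b Named character vectors of distal-leader sequences by
#'   gene.
#' @param threshold Jaccard threshold (default 0.6).
#' @param n_shuffles,seed Passed to [align_uorf_to_tl()].
#' @return Data frame of pairs: `gene_a`, `gene_b`, `idx_a`, `idx_b` (row
#'   indices into the call tables), `class = "sequence"`, `jaccard`,
#'   `alignment_score`, `z_score`.
#' @export
sequence_homologs <- function(calls_a, calls_b, gene_pairs, tl_a, tl_b,
                              threshold = 0.6, n_shuffles = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(calls_a))) {
    ga <- calls_a$gene_id[i]
    gb <- gene_pairs$gene_b[match(ga, gene_pairs$gene_a)]
    if (is.na(gb) || !gb %in% names(tl_b)) next
    jb <- which(calls_b$gene_id == gb)
    if (!length(jb)) next
    useq <- substr(tl_a[[ga]], calls_a$start_pos[i] + 1L, calls_a$stop_pos[i] + 1L)
    if (nchar(useq) == 0 || nchar(tl_b[[gb]]) == 0) next
    aln <- align_uorf_to_tl(useq, tl_b[[gb]], n_shuffles = n_shuffles)
    mapped <- c(aln$mapped_start, aln$mapped_end)
    jac <- vapply(jb, function(j) {
      jaccard_index(mapped, c(calls_b$start_pos[j], calls_b$stop_pos[j] + 1L))
    }, numeric(1))
    best <- which(jac == max(jac))[1]
    if (jac[best] >= threshold) {
      out[[length(out) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, idx_a = i, idx_b = jb[best],
        class = "sequence", jaccard = jac[best],
        alignment_score = aln$score, z_score = aln$z_score)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      idx_a = integer(0), idx_b = integer(0),
                      class = character(0), jaccard = numeric(0),
                      alignment_score = numeric(0), z_score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Positional homologs between two species' uORF calls
#'
#' Start and stop codon positions are measured as distances upstream of the
#' mORF start; two calls pair when the start distances or (by default) the
#' stop distances agree within `tol_nt` (default 5).  Pairs already
#' classified as sequence homologs are excluded: sequence conservation takes
#' precedence.
#'
#' @inheritParams sequence_homologs
#' @param leader_len_a,leader_len_b Named integer vectors of distal-leader
#'   lengths by gene.
#' @param tol_nt Position tolerance in nucleotides (default 5).
#' @param rule `"or"` (default: start or stop within tolerance) or `"and"`.
#' @param exclude Data frame of already-made pairs (`idx_a`, `idx_b`), e.g.
#'   [sequence_homologs()] output.
#' @return Data frame like [sequence_homologs()] with `class = "position"`
#'   and `NA` alignment columns.
#' @export
position_homologs <- function(calls_a, calls_b, gene_pairs,
                              leader_len_a, leader_len_b, tol_nt = 5L,
                              rule = c("or", "and"), exclude = NULL) {
  rule <- match.arg(rule)
  out <- list()
  for (i in seq_len(nrow(calls_a))) {
    ga <- calls_a$gene_id[i]
    gb <- gene_pairs$gene_b[match(ga, gene_pairs$gene_a)]
    if (is.na(gb)) next
    jb <- which(calls_b$gene_id == gb)
    if (!length(jb)) next
    da_start <- leader_len_a[[ga]] - calls_a$start_pos[i]
    da_stop <- leader_len_a[[ga]] - calls_a$stop_pos[i] - 1L
    db_start <- leader_len_b[[gb]] - calls_b$start_pos[jb]
    db_stop <- leader_len_b[[gb]] - calls_b$stop_pos[jb] - 1L
    ds <- abs(da_start - db_start); de <- abs(da_stop - db_stop)
    hit <- if (rule == "or") ds <= tol_nt | de <= tol_nt
           else ds <= tol_nt & de <= tol_nt
    if (!is.null(exclude) && nrow(exclude)) {
      hit <- hit & !(paste(i, jb) %in% paste(exclude$idx_a, exclude$idx_b))
    }
    if (!any(hit)) next
    best <- jb[hit][which.min((ds + de)[hit])]
    out[[length(out) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, idx_a = i, idx_b = best,
      class = "position", jaccard = NA_real_,
      alignment_score = NA_real_, z_score = NA_real_)
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      idx_a = integer(0), idx_b = integer(0),
                      class = character(0), jaccard = numeric(0),
                      alignment_score = numeric(0), z_score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Classify cross-species uORF homolog pairs
#'
#' Runs [sequence_homologs()] then [position_homologs()] on the remaining
#' calls; a pair satisfying both definitions is labeled `sequence`
#' (precedence rule), so every pair carries exactly one class.
#'
#' @inheritParams sequence_homologs
#' @inheritParams position_homologs
#' @return Combined pair data frame.
#' @export
classify_homologs <- function(calls_a, calls_b, gene_pairs, tl_a, tl_b,
                              threshold = 0.6, tol_nt = 5L, rule = "or",
                              n_shuffles = 100L, seed = NULL) {
  seq_pairs <- sequence_homologs(calls_a, calls_b, gene_pairs, tl_a, tl_b,
                                 threshold = threshold,
                                 n_shuffles = n_shuffles, seed = seed)
  remaining_a <- setdiff(seq_len(nrow(calls_a)), seq_pairs$idx_a)
  leader_len_a <- vapply(tl_a, nchar, integer(1))
  leader_len_b <- vapply(tl_b, nchar, integer(1))
  pos_pairs <- position_homologs(
    calls_a[remaining_a, , drop = FALSE],
    calls_b, gene_pairs, leader_len_a, leader_len_b,
    tol_nt = tol_nt, rule = rule)
  if (nrow(pos_pairs)) {
    pos_pairs$idx_a <- remaining_a[pos_pairs$idx_a]
  }
  rbind(seq_pairs, pos_pairs[names(seq_pairs)])
}

#' Count homolog triplets across three species
#'
#' A triplet is a connected component of pairwise homolog links that spans
#' all three species.  Nodes are `species:gene:index` call identifiers.
#'
#' @param pair_tables Named list of pair data frames, names like `"A_B"`,
#'   `"B_C"`, `"A_C"` (species labels separated by `_`), each as returned by
#'   [classify_homologs()].
#' @return List with `n_triplets` and `components` (list of member node
#'   vectors for spanning components).
#' @export
homolog_triplets <- function(pair_tables) {
  edges <- list()
  for (nm in names(pair_tables)) {
    sp <- strsplit(nm, "_", fixed = TRUE)[[1]]
    tab <- pair_tables[[nm]]
    if (!nrow(tab)) next
    edges[[nm]] <- cbind(paste0(sp[1], ":", tab$gene_a, ":", tab$idx_a),
                         paste0(sp[2], ":", tab$gene_b, ":", tab$idx_b))
  }
  if (!length(edges)) return(list(n_triplets = 0L, components = list()))
  E <- do.call(rbind, edges)
  nodes <- unique(c(E))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(E))) {
    a <- find(match(E[k, 1], nodes)); b <- find(match(E[k, 2], nodes))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  comps <- split(nodes, comp)
  spanning <- Filter(function(members) {
    length(unique(sub(":.*$", "", members))) >= 3L
  }, comps)
  list(n_triplets = length(spanning), components = unname(spanning))
}
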