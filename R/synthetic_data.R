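#' Simulation configuration
#'
#' Defines the synthetic study conditions: a yeast-like transcriptome of
#' compact single-exon genes with short lognormal leaders (median about 50
#' nt), one to three TSS clusters per gene with Dirichlet usage, planted
#' uORFs whose ribosome density scales with start-codon strength (AUG > UUG >
#' other near-cognates), three or more replicate Ribo-seq tracks with 3-nt
#' periodicity, and a diverged sister species sharing a configurable subset
#' of planted uORFs.
#'
#' @param n_genes Number of genes (default 50).
#' @param leader_meanlog,leader_sdlog Lognormal parameters of the leader
#'   length (defaults give median 50 nt).
#' @param morf_codons Range of mORF lengths in codons, excluding the stop
#'   (default 60-150).
#' @param utr3_len Range of 3' UTR lengths (default 60-120).
#' @param max_tss_clusters Up to this many TSS isoforms per gene (default 3).
#' @param dirichlet_alpha Concentration of the per-gene TSS usage Dirichlet
#'   (default 2).
#' @param planted_fraction Fraction of genes receiving one planted uORF
#'   (default 0.5).
#' @param codon_mix Named probabilities over planted start codons.
#' @param uorf_codons Range of planted uORF lengths in codons including the
#'   stop (default 4-10, i.e. 12-30 nt).
#' @param uorf_multiplier Planted uORF P-site density as a multiple of the
#'   leader background (default 5).
#' @param codon_scale Relative density by start-codon class: AUG strongest,
#'   UUG intermediate, other near-cognates weakest.  Set all to 1 for a
#'   homogeneous planting.
#' @param start_peak Extra density factor on the planted first codon
#'   (initiation peak, default 2).
#' @param n_replicates Ribo-seq replicates (default 3; the caller requires
#'   at least 3).
#' @param leader_noise_rate Uniform leader background, P-sites per nt per
#'   replicate (default 0.2).
#' @param morf_density_meanlog,morf_density_sdlog Lognormal per-gene mORF
#'   P-site density (per nt per replicate).
#' @param periodicity Fraction of an ORF codon's P-site mass on frame 0
#'   (default 0.9).
#' @param rna_rate RNA-seq coverage rate per nt (default 0.5), scaled by the
#'   gene's relative expression.
#' @param n_species Number of simulated species (1-3, default 2).
#' @param divergence Per-nucleotide substitution rate between species
#'   (default 0.1).
#' @param shared_fraction Probability a planted uORF is preserved (shared)
#'   in the sister species (default 0.7).
#' @param seed Mandatory integer seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 50L,
                              leader_meanlog = log(50), leader_sdlog = 0.45,
                              morf_codons = c(60L, 150L),
                              utr3_len = c(60L, 120L),
                              max_tss_clusters = 3L,
                              dirichlet_alpha = 2,
                              planted_fraction = 0.5,
                              codon_mix = c(ATG = 0.35, TTG = 0.25, CTG = 0.08,
                                            GTG = 0.08, ACG = 0.08, ATA = 0.06,
                                            ATT = 0.05, ATC = 0.05),
                              uorf_codons = c(4L, 10L),
                              uorf_multiplier = 5,
                              codon_scale = c(ATG = 1, TTG = 0.8, other = 0.6),
                              start_peak = 2,
                              n_replicates = 3L,
                              leader_noise_rate = 0.2,
                              morf_density_meanlog = log(0.5),
                              morf_density_sdlog = 0.5,
                              periodicity = 0.9,
                              rna_rate = 0.5,
                              n_species = 2L,
                              divergence = 0.1,
                              shared_fraction = 0.7,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory in simulation_config()")
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            periodicity >= 0, periodicity <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            divergence >= 0, divergence <= 1,
            n_species >= 1L, n_species <= 3L)
  cfg <- as.list(environment())
  cfg$codon_mix <- codon_mix / sum(codon_mix)
  structure(cfg, class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")
.NONSTOP_CODONS <- local({
  all3 <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# random in-frame codon string with no stop codons, n_codons long
.random_orf_body <- function(n_codons) {
  if (n_codons <= 0) return("")
  paste(sample(.NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Generate a synthetic transcriptome with planted uORFs
#'
#' Builds one or more "species": a genome FASTA-ready sequence set, one
#' transcript model per gene, and a truth table of planted uORFs.  Leaders
#' are random sequence (so they contain decoy start codons without
#' translation) with at most one planted uORF written in as start codon +
#' stop-free body + stop codon, guaranteed to be recovered by
#' [enumerate_candidates()].  Sister species are derived by point-mutating
#' the first species at the configured divergence rate; planted uORFs
#' flagged as shared keep their start and stop codons intact and body
#' mutations that would introduce an in-frame stop are suppressed, while
#' non-shared planted uORFs have their start codon overwritten with the
#' non-initiating AGG triplet.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes` (per species, a named list of chromosome
#'   strings), `models` (per species, named list of `transcript_model`),
#'   and `truth` (data frame: `gene_id`, `start_pos`, `stop_pos`,
#'   `start_codon`, `multiplier`, plus one logical `present_<species>`
#'   column per species).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  species_names <- c("A", "B", "C")[seq_len(config$n_species)]

  leader_len <- pmax(12L, as.integer(round(stats::rlnorm(
    n, config$leader_meanlog, config$leader_sdlog))))
  morf_codons <- sample(seq(config$morf_codons[1], config$morf_codons[2]), n, TRUE)
  utr3_len <- sample(seq(config$utr3_len[1], config$utr3_len[2]), n, TRUE)
  strands <- sample(c("+", "-"), n, TRUE)
  planted <- stats::runif(n) < config$planted_fraction

  genes <- vector("list", n)
  truth_rows <- list()
  for (i in seq_len(n)) {
    ll <- leader_len[i]
    leader <- .random_seq(ll)
    uorf <- NULL
    if (planted[i]) {
      nc <- sample(seq(config$uorf_codons[1], config$uorf_codons[2]), 1L)
      len <- 3L * nc
      if (len + 3L <= ll) {
        start_codon <- sample(names(config$codon_mix), 1L, prob = config$codon_mix)
        s <- sample.int(ll - len + 1L, 1L) - 1L       # 0-based start
        body <- .random_orf_body(nc - 2L)
        stopc <- sample(stop_codons(), 1L)
        substr(leader, s + 1L, s + len) <- paste0(start_codon, body, stopc)
        scl <- if (start_codon == "ATG") config$codon_scale[["ATG"]]
               else if (start_codon == "TTG") config$codon_scale[["TTG"]]
               else config$codon_scale[["other"]]
        uorf <- list(start_pos = s, stop_pos = s + len - 1L,
                     start_codon = start_codon,
                     multiplier = config$uorf_multiplier * scl)
      }
    }
    morf <- paste0("ATG", .random_orf_body(morf_codons[i] - 1L), "TAA")
    utr3 <- .random_seq(utr3_len[i])
    genes[[i]] <- list(gene_id = sprintf("gene%03d", i), strand = strands[i],
                       leader = leader, morf = morf, utr3 = utr3,
                       leader_len = ll, uorf = uorf)
    if (!is.null(uorf)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = genes[[i]]$gene_id, start_pos = uorf$start_pos,
        stop_pos = uorf$stop_pos, start_codon = uorf$start_codon,
        multiplier = uorf$multiplier)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(0), start_pos = integer(0),
               stop_pos = integer(0), start_codon = character(0),
               multiplier = numeric(0))
  truth$present_A <- rep(TRUE, nrow(truth))

  # sister species: point-mutate leaders/UTRs/mORF bodies
  species_genes <- list(A = genes)
  for (sp in species_names[-1]) {
    shared_sp <- stats::runif(nrow(truth)) < config$shared_fraction
    names(shared_sp) <- truth$gene_id
    gsp <- lapply(genes, function(g) {
      g2 <- g
      g2$leader <- .mutate_seq(g$leader, config$divergence)
      g2$utr3 <- .mutate_seq(g$utr3, config$divergence)
      g2$morf <- .mutate_orf(g$morf, config$divergence)
      if (!is.null(g$uorf)) {
        is_shared <- isTRUE(shared_sp[[g$gene_id]])
        g2$leader <- .restore_planted(g2$leader, g$leader, g$uorf,
                                      shared = is_shared)
        if (!is_shared) g2$uorf <- NULL
      }
      g2
    })
    species_genes[[sp]] <- gsp
    truth[[paste0("present_", sp)]] <- shared_sp
  }

  genomes <- list(); models <- list()
  for (sp in species_names) {
    res <- .assemble_genome(species_genes[[sp]], config)
    genomes[[sp]] <- res$genome
    models[[sp]] <- res$models
  }
  list(genomes = genomes, models = models, truth = truth,
       species = species_names, config = config)
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

# mutate an ORF body without creating in-frame stops or touching start/stop codons
.mutate_orf <- function(orf, rate) {
  n <- nchar(orf)
  if (rate <= 0 || n <= 6L) return(orf)
  body <- substr(orf, 4L, n - 3L)
  codons <- substring(body, seq(1, nchar(body), 3), seq(3, nchar(body), 3))
  for (k in seq_along(codons)) {
    mut <- .mutate_seq(codons[k], rate)
    if (!mut %in% stop_codons()) codons[k] <- mut
  }
  paste0(substr(orf, 1, 3), paste(codons, collapse = ""), substr(orf, n - 2L, n))
}

# after leader mutation, restore (shared) or kill (private) a planted uORF
.restore_planted <- function(mut_leader, orig_leader, uorf, shared) {
  s <- uorf$start_pos; e <- uorf$stop_pos
  if (!shared) {
    substr(mut_leader, s + 1L, s + 3L) <- "AGG"
    return(mut_leader)
  }
  # keep start and stop codons; suppress body mutations that create in-frame stops
  substr(mut_leader, s + 1L, s + 3L) <- substr(orig_leader, s + 1L, s + 3L)
  substr(mut_leader, e - 1L, e + 1L) <- substr(orig_leader, e - 1L, e + 1L)
  if (e - 5L < s + 3L) return(mut_leader)
  body_starts <- seq(s + 3L, e - 5L, by = 3L)
  for (b in body_starts) {
    cod <- substr(mut_leader, b + 1L, b + 3L)
    if (cod %in% stop_codons()) {
      substr(mut_leader, b + 1L, b + 3L) <- substr(orig_leader, b + 1L, b + 3L)
    }
  }
  mut_leader
}

# place genes along one chromosome and build transcript models
.assemble_genome <- function(genes, config) {
  gap_min <- 100L; gap_max <- 200L
  chrom <- "chrI"
  pieces <- character(0)
  models <- list()
  cursor <- 0L
  for (g in genes) {
    gap <- sample(seq(gap_min, gap_max), 1L)
    pieces <- c(pieces, .random_seq(gap))
    cursor <- cursor + gap
    tx <- paste0(g$leader, g$morf, g$utr3)
    txlen <- nchar(tx)
    ll <- g$leader_len
    ml <- nchar(g$morf)
    if (g$strand == "+") {
      pieces <- c(pieces, tx)
      tss_distal <- cursor
      morf_start <- cursor + ll
      morf_stop <- cursor + ll + ml - 1L
      utr3_iv <- c(morf_stop + 1L, cursor + txlen)
    } else {
      pieces <- c(pieces, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx))))
      tss_distal <- cursor + txlen - 1L
      morf_start <- cursor + txlen - ll - 1L
      morf_stop <- cursor + txlen - ll - ml
      utr3_iv <- c(cursor, morf_stop)
    }
    # extra TSS isoforms strictly downstream of the distal one, inside the leader
    n_iso <- sample.int(config$max_tss_clusters, 1L)
    extra_max <- max(ll - 12L, 0L)
    offsets <- 0L
    if (n_iso > 1L && extra_max >= 5L) {
      pool <- seq(5L, extra_max)
      k <- min(n_iso - 1L, length(pool))
      offsets <- c(0L, sort(pool[sample.int(length(pool), k)]))
    }
    tss <- if (g$strand == "+") tss_distal + offsets else tss_distal - offsets
    usage <- stats::rgamma(length(offsets), shape = config$dirichlet_alpha)
    usage <- usage / sum(usage)
    pa_pos <- if (g$strand == "+") cursor + txlen - 1L else cursor
    models[[g$gene_id]] <- transcript_model(
      gene_id = g$gene_id, chrom = chrom, strand = g$strand,
      morf_start = morf_start, morf_stop = morf_stop,
      tss = tss, tss_usage = usage,
      pa = pa_pos, pa_usage = 1, utr3 = utr3_iv)
    cursor <- cursor + txlen
  }
  # terminal flank so no transcript abuts the chromosome end
  pieces <- c(pieces, .random_seq(gap_min))
  genome <- list(paste(pieces, collapse = ""))
  names(genome) <- chrom
  list(genome = genome, models = models)
}

#' Simulate end-seq read-end pileups
#'
#' Read-end counts are Poisson background genome-wide plus multinomial signal
#' at the true TSS (5' pileup) and pA (3' pileup) positions with a jitter of
#' at most 2 nt.
#'
#' @param models Named list of `transcript_model` (one species).
#' @param genome_len Chromosome length in nt.
#' @param depth Signal reads per gene (default 1000).
#' @param background_rate Poisson background per position per strand
#'   (default 0.05).
#' @param seed Integer seed.
#' @return List with `tss` and `pa`, each a list of `end_pileup` per strand.
#' @export
simulate_end_seq <- function(models, genome_len, depth = 1000L,
                             background_rate = 0.05, seed = 1L) {
  set.seed(seed)
  jitter_prob <- c(0.05, 0.2, 0.5, 0.2, 0.05)
  make_side <- function(kind) {
    out <- list()
    for (st in c("+", "-")) {
      counts <- stats::rpois(genome_len, background_rate)
      for (m in models) {
        if (m$strand != st) next
        sites <- if (kind == "tss") m$tl_isoforms else m$pa_sites
        if (!nrow(sites)) next
        pos_col <- if (kind == "tss") sites$tss else sites$pa
        alloc <- as.vector(stats::rmultinom(1, depth, sites$usage_fraction))
        for (k in seq_along(pos_col)) {
          if (alloc[k] == 0) next
          jit <- sample(-2:2, alloc[k], replace = TRUE, prob = jitter_prob)
          p <- pos_col[k] + jit
          p <- p[p >= 0 & p < genome_len]
          tb <- table(p)
          idx <- as.integer(names(tb)) + 1L
          counts[idx] <- counts[idx] + as.integer(tb)
        }
      }
      covered <- which(counts > 0)
      out[[st]] <- end_pileup(models[[1]]$chrom, st, covered - 1L, counts[covered])
    }
    out
  }
  list(tss = make_side("tss"), pa = make_side("pa"))
}

#' Simulate replicate Ribo-seq P-site tracks and RNA coverage
#'
#' Per gene, a shared mean track is built in transcript coordinates: uniform
#' leader noise, 3-nt periodic mORF occupancy at a gene-specific lognormal
#' rate, and (for planted uORFs present in the species) periodic uORF
#' occupancy at `multiplier x leader background` with an initiation peak on
#' the first codon.  Replicates are independent Poisson draws around the
#' shared means; RNA coverage is an independent Poisson draw around the
#' gene's expression-scaled rate.
#'
#' @param models Named list of `transcript_model` (one species).
#' @param truth Truth table from [generate_transcriptome()]; only rows
#'   present in this species are planted (pass the species' presence column
#'   as `present`).
#' @param config A [simulation_config()].
#' @param present Logical vector over `truth` rows (default all).
#' @param seed Integer seed.
#' @return Named list (by gene): `tracks` (list of `n_replicates` integer
#'   vectors), `rna` (integer vector), `leader_len`, `morf_len`.
#' @export
simulate_profiling <- function(models, truth, config,
                               present = rep(TRUE, nrow(truth)), seed = 1L) {
  set.seed(seed)
  out <- list()
  truth_use <- truth[present, , drop = FALSE]
  for (m in models) {
    ll <- leader_length(m); ml <- morf_length(m)
    txlen <- ll + ml
    mu <- rep(config$leader_noise_rate, txlen)
    d_g <- stats::rlnorm(1, config$morf_density_meanlog, config$morf_density_sdlog)
    # periodic mORF occupancy: codon mass 3*d_g split by periodicity
    codon_mass <- 3 * d_g
    frame_mass <- c(config$periodicity,
                    (1 - config$periodicity) / 2,
                    (1 - config$periodicity) / 2) * codon_mass
    if (ml >= 3L) {
      mu[(ll + 1L):txlen] <- rep(frame_mass, length.out = ml)
    }
    tr <- truth_use[truth_use$gene_id == m$gene_id, , drop = FALSE]
    if (nrow(tr) == 1L) {
      s <- tr$start_pos; e <- tr$stop_pos
      u_codon_mass <- 3 * tr$multiplier * config$leader_noise_rate
      u_mass <- c(config$periodicity,
                  (1 - config$periodicity) / 2,
                  (1 - config$periodicity) / 2) * u_codon_mass
      seg <- rep(u_mass, length.out = e - s + 1L)
      seg[1:3] <- seg[1:3] * config$start_peak
      mu[(s + 1L):(e + 1L)] <- config$leader_noise_rate + seg
    }
    tracks <- lapply(seq_len(config$n_replicates),
                     function(r) stats::rpois(txlen, mu))
    rel_expr <- d_g / exp(config$morf_density_meanlog)
    rna <- stats::rpois(txlen, config$rna_rate * rel_expr)
    out[[m$gene_id]] <- list(tracks = tracks, rna = rna,
                             leader_len = ll, morf_len = ml)
  }
  out
}

#' Write a simulated species to disk
#'
#' Emits genome FASTA, gene/CDS GFF3, TSS and pA BED6, and the truth table
#' TSV, all plain text and byte-deterministic for a fixed config and seed.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sp in sim$species) {
    fa <- file.path(dir, paste0("species_", sp, ".fa"))
    g <- sim$genomes[[sp]]
    writeLines(c(paste0(">", names(g)[1]),
                 substring(g[[1]], seq(1, nchar(g[[1]]), 60),
                           pmin(seq(60, nchar(g[[1]]) + 59, 60), nchar(g[[1]])))),
               fa)
    gff <- file.path(dir, paste0("species_", sp, ".gff3"))
    tlb <- file.path(dir, paste0("species_", sp, "_tss.bed"))
    pab <- file.path(dir, paste0("species_", sp, "_pa.bed"))
    write_transcript_models(sim$models[[sp]], gff, tlb, pab)
    paths <- c(paths, fa, gff, tlb, pab)
  }
  tt <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tt))
}
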