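---
title: "Methods: statistically controlled uORF identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistically controlled uORF identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfseqr)
```

# The problem

Upstream open reading frames (uORFs) are short coding elements in transcript
leaders (5' UTRs) that regulate translation of the downstream main ORF
(mORF).  Besides canonical AUG starts, translation can initiate at
near-cognate codons (NCCs) — the single-nucleotide variants of AUG.  The
working NCC set here has seven members (UUG, CUG, GUG, ACG, AUA, AUU, AUC);
AGG is treated as non-initiating.  Because the sequence requirements are so
weak, heuristic scans of ribosome profiling (Ribo-seq) data produce
thousands of NCC uORF candidates with no statistical control.  `uorfseqr`
provides that control: it scores candidates with a regression trained on
replicate-to-replicate detection and calibrates significance against a
randomized null, reporting empirical q-values.

The package also covers the stages around that core: transcript-boundary
mapping from 5'/3' end-sequencing, P-site assignment, cross-species homolog
classification, descriptive statistics, and a synthetic-data generator with
planted ground truth that exercises the whole pipeline.

# Transcript-boundary peak calling

TL-seq and pA-seq produce single-nucleotide read-end pileups.  True TSS and
pA sites appear as sharp spikes over a locally flat background.  We model the
background as a piecewise-constant Poisson rate estimated by first-order
trend filtering: over log-rates $\theta_i$ we minimize

$$\sum_i \left[e^{\theta_i} - c_i \theta_i\right]
  + \lambda \sum_i |\theta_{i+1} - \theta_i|,$$

the negative Poisson log-likelihood plus a total-variation penalty on
adjacent log-rate differences.  The convex problem is solved by iteratively
reweighted least squares; each quadratic subproblem is a weighted 1-D fused
lasso solved exactly by ADMM with an $O(n)$ tridiagonal solve (implemented
in C++).  The ADMM split variable is exactly sparse, so its zero pattern
defines the fused segmentation; the reported background is the segment-wise
Poisson MLE with outliers excluded (post-selection debiasing).  Two limits
anchor the estimator and are asserted in the test suite: as
$\lambda \to \infty$ the fit is the window's global mean rate, and as
$\lambda \to 0$ it interpolates the counts.

**Outlier detection.**  A background estimate must not absorb the signal it
is meant to test.  Positions are first flagged against the window's global
mean rate (Poisson upper-tail $p < 10^{-6}$), then iteratively against the
leave-self-out rate of their fused segment; flagged positions are excluded
from the fit and the loop repeats until the flag set stabilizes (flags
accumulate monotonically, so at most 20 rounds).  Without the leave-self-out
rule, an isolated spike can form its own one-position segment and vouch for
itself.

**Calling.**  Each covered position gets an upper-tail Poisson p-value under
its local background; Benjamini–Hochberg is applied across all tested
(count $\ge 1$) positions and peaks are reported at $q \le \beta$ with
$\beta = 0.001$ by default.  Zero-count positions are never tested, so the
FDR universe is the covered search space.  Long pileups are processed in
2 kb tiles, each with its own background; $\lambda$ defaults to a per-window
choice, halving from an upper bound until the fit shows at least two levels.
Called peaks are clustered single-linkage within 25 nt; a cluster's
representative is its maximal-count member (upstream-first tie-break) and
its usage fraction is its share of the gene's total.  Leader-length
summaries (usage-weighted average length, cross-species CV with the 0.06
lowest-decile conservation cutoff) operate on these clusters.

# Candidate enumeration and features

Leaders from the most distal TSS are scanned at every position for the eight
start codons; each start is paired with its first in-frame stop, sought in
the leader-plus-mORF context so candidates whose stop lies at or beyond the
mORF start are still enumerated (flagged `overlaps_morf` and excluded from
default calling).  Starts with no in-frame stop (would-be N-terminal
extensions) are not candidates.  Enumeration is verified exactly against a
brute-force position-scan oracle.

Each candidate is scored for 18 features from the pooled (replicate-summed)
P-site track, the RNA-seq coverage track, and leader geometry; see
`uorf_feature_names()` for the list.  They cover occupancy (density,
start-codon count, 3-nt periodicity, codon coverage, enrichment over leader
and mORF backgrounds, boundary signals, RNA abundance, translation
efficiency) and geometry (length, distances to the TSS and mORF, relative
position, leader length).  Start-codon identity is deliberately *not* a
feature: including it would bias the model towards AUG and against
near-cognate starts.  Log-scale features use $\log_2(x+1)$; ratio features
with an empty denominator region impute one count over that region; the
in-frame fraction of a candidate with no reads is imputed to 0 and paired
with a `has_coverage` indicator.

# The detection regression and empirical FDR

For each replicate, a candidate is "detected" by a simple heuristic (start
codon count $\ge 1$, total $\ge 4$, in-frame fraction $\ge 0.5$; all
configurable).  The regression target is the fraction of replicates in which
the candidate is detected — which is why at least three biological
replicates are required, and the fit refuses fewer.  A ridge-regularized
linear regression (penalty $10^{-3}$ on standardized features; the features
are collinear by construction) maps features to that target; weights are
estimated independently for each experiment.  Scores are the fitted values.

Significance comes from a randomized null: within each leader, each
replicate's P-site counts are uniformly re-positioned (totals preserved, the
mORF untouched, so expression level is retained while uORF-specific
structure — periodicity, start peaks, local enrichment — is destroyed),
features are recomputed, and the already-trained model is applied; 10
permutations are pooled by default.  For a threshold $s$,

$$\widehat{\mathrm{FDR}}(s) =
  \frac{(1 + \#\{\text{null} \ge s\})/N_{\text{null}}}
       {\max(1, \#\{\text{real} \ge s\})/N_{\text{real}}},$$

and a candidate's q-value is the minimum of $\widehat{\mathrm{FDR}}$ over
thresholds at or below its score, clipped to $[0,1]$; the $+1$ pseudocount
keeps q-values positive.  Calls are made at $q \le \beta$ with
$\beta = 0.05$; overlapping or nested significant candidates are resolved
greedily by score (ties: longer, then more upstream), so the reported set is
pairwise non-overlapping.  Candidates with zero pooled P-sites are scored
but flagged `no_signal`.

# Cross-species homology

For homologous gene pairs, a uORF from one species is locally aligned
(Smith–Waterman) into the other species' leader under HOXD70 substitution
scores with gap open 400 / extend 30.  Pairwise local alignment is used
because the operation aligns one short uORF against one leader; a
multiple-alignment engine adds nothing here.  A Z-score against 100
mononucleotide shuffles of the uORF breaks ties between alternative
placements.  If the mapped interval overlaps a called uORF in the other
species with Jaccard index $\ge 0.6$, the pair is a *sequence homolog*.
Remaining calls are compared by position: start and stop distances upstream
of the mORF start; agreement within 5 nt of either (OR rule by default; AND
available) makes a *positional homolog*.  A pair satisfying both is labeled
sequence — precedence guarantees every pair has exactly one class.  Across
three species, triplets are counted as connected components of pairwise
links spanning all species.

# Descriptive statistics

Triplet observed/expected ratios use overlapping (stride-1) 3-nt windows in
leaders versus 3' UTRs — stride 1 because depletion/enrichment signals are
strongest with the maximal window count.  Transcript inclusion of a uORF is
the summed usage of TSS isoforms at or upstream of its start codon.
Translation-efficiency group comparisons use two-sided Wilcoxon rank-sum
tests with BH adjustment.  The RBP metagene sums binding-site overlaps in
3-nt steps around TISs; the expected profile is the mean of 1000 draws
resampling TIS positions uniformly within each gene's eligible region and
site positions uniformly within the transcript (the named sampling objects;
the uniform measure is our choice).  Only genes whose region encloses a step
contribute to it, and leader regions are truncated 15 nt upstream of the
mORF start so main-ORF initiation-site protein contacts are not attributed
to uORFs.

# The synthetic-data generator

The generator defines the study conditions the tests run under; its
defaults are fixed and not tuned per test:

* 50 genes per species, mixed strands, single-exon (yeast-like gene
  structure; splicing-aware leaders are out of scope);
* leader lengths lognormal with median 50 nt (short yeast leaders);
* 1–3 TSS clusters per gene with Dirichlet (concentration 2) usage;
* half the genes carry one planted uORF of 4–10 codons; start codons drawn
  with AUG and UUG most frequent; planted ribosome density is 5× the leader
  background, scaled by start-codon strength (AUG 1.0 > UUG 0.8 > other
  NCC 0.6), with a 2× initiation peak on the first codon;
* 3 replicates of Poisson P-site tracks with in-frame fraction 0.9 over
  ORFs, leader background 0.2 P-sites/nt/replicate, per-gene lognormal mORF
  density (median 0.5/nt);
* sister species at 10% nucleotide divergence, 70% of planted uORFs shared
  (start/stop codons preserved, stop-creating body mutations suppressed);
  non-shared planted uORFs have their start codon overwritten with AGG;
* end-seq pileups as Poisson background (0.05/nt/strand) plus multinomial
  signal at true sites with ±2 nt jitter.

These sizes keep every property check comfortably fast while leaving enough
candidates (a few hundred decoy start codons per run) for the regression and
the null to be meaningful.  What the generator does *not* emulate: sequence-
specific library bias, overdispersion beyond Poisson (a negative-binomial
knob exists but is off by default), condition-dependent TSS switching,
splicing, and real leader-sequence composition.  Passing tests therefore
show the method is correct and calibrated under its own model assumptions —
not that real libraries are free of artifacts the features cannot see.

# Numerical and design choices

* **Coordinates** are 0-based half-open internally; GFF3 converts at the I/O
  boundary; BED is native.  RNA-alphabet codons are handled as DNA
  internally.
* **Recovery matching** in truth-based evaluation is by gene and stop codon:
  in-frame candidates sharing a stop are one ORF family, and the start
  assignment among adjacent near-cognate codons is intrinsically ambiguous
  (AUUG contains two overlapping NCCs), so family-level identity is the
  meaningful criterion.
* **ADMM tolerances**: inner solves run to a 1e-9 residual with warm starts
  across IRLS iterations and λ values, plus a final full-convergence polish
  so the segmentation pattern is trustworthy; the λ→∞/λ→0 limit tests pass
  at 1e-6 relative.
* **Degenerate inputs**: all-zero windows return zero background and no
  outliers; empty leaders return empty candidate sets; constant detection
  targets and fewer than three replicates are refused with explicit errors;
  zero-coverage q-value inputs error on an empty null.
* **Determinism**: every stochastic step takes a seed; the pipeline derives
  stage seeds from the config seed by fixed offsets, and two runs with the
  same config produce byte-identical output tables.
* **Interface shape**: the detection regression is a classed model object
  (`uorf_regression`) with the standard `print`/`summary`/`coef`/`predict`/
  `residuals`/`plot` methods; pipeline stages are plain functions, with
  `run_uorfseqr()` and a thin `inst/cli/uorfseqr.R` script as entry points.

# Known limitations

Candidates overlapping the mORF start are enumerated but not called by
default; N-terminal extensions are out of scope.  Multi-exon genes are
excluded at annotation load.  The homolog gene pairing is taken as input —
no orthology inference.  The per-experiment regression weights do not
transfer across experiments by design.  Real-data FDR depends on the null
permutation capturing the right artifact structure; the uniform
re-positioning preserves totals but not, for example, sequence-driven
ligation bias.

# A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 30, seed = 42)
res <- simulate_experiment(cfg)
print(res$experiment)
summary(res$experiment$model)
evaluate_calls(res$experiment$calls, res$truth)
```
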