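# uorfseqr

Statistically controlled identification of AUG and near-cognate-codon (NCC)
upstream open reading frames (uORFs) from replicate ribosome profiling data,
with the supporting computational stack around it: transcript-boundary
mapping from 5'/3' end-sequencing, P-site assignment, cross-species uORF
homology classification, and a synthetic-data generator with planted ground
truth.

## Who this is for

Groups analyzing yeast-like (compact, mostly single-exon) transcriptomes
with **three or more biological replicates** of Ribo-seq plus RNA-seq, who
want uORF calls — including weak NCC-initiated ones — with an empirical
false discovery rate instead of rule-of-thumb heuristics, and who want to
compare those calls across related species.

## The method

**Transcript boundaries.** TL-seq/pA-seq read-end pileups are modeled as
sharp spikes over a piecewise-constant Poisson background estimated by
first-order Poisson trend filtering with outlier detection: minimize over
log-rates θ

    Σᵢ [exp(θᵢ) − cᵢ θᵢ] + λ Σᵢ |θᵢ₊₁ − θᵢ|

(IRLS outer loop, exact weighted fused-lasso inner solve in C++). Each
covered position gets an upper-tail Poisson p-value under its local
background; Benjamini–Hochberg across tested positions calls TSS/pA peaks at
q ≤ β = 0.001, clustered in 25-nt windows with usage fractions.

**uORF calling.** Transcript leaders are scanned for AUG and the seven
initiating NCC codons (UUG, CUG, GUG, ACG, AUA, AUU, AUC; AGG is
non-initiating) with in-frame stops. Each candidate is scored for 18
occupancy and geometry features — start-codon identity deliberately excluded
to avoid AUG/NCC bias — and a ridge-regularized linear regression is trained
per experiment to predict the fraction of replicates in which the candidate
is detected. Significance comes from a randomized null (P-sites uniformly
re-positioned within each leader, per replicate, totals preserved):

    FDR(s) = [(1 + #null ≥ s)/N_null] / [max(1, #real ≥ s)/N_real]

with q = the minimum FDR over score thresholds at or below the candidate's
score. Calls are made at q ≤ β = 0.05; overlapping/nested significant
candidates resolve greedily by score.

**Homology.** For homologous gene pairs, uORFs are locally aligned into the
other species' leader (HOXD70 scores, shuffle Z-scores for tie-breaks);
Jaccard overlap ≥ 0.6 with a called uORF makes a *sequence homolog*, start
or stop distance from the mORF within ±5 nt makes a *positional homolog*,
and sequence takes precedence.

## A worked example

```r
library(uorfseqr)
cfg <- simulation_config(n_genes = 30, seed = 42)  # planted ground truth
res <- simulate_experiment(cfg)                    # simulate + enumerate + call
print(res$experiment)
#> uORF-calling experiment: 84 candidates, 12 significant uORFs at beta = 0.05
#>   by start codon: ACG=1 ATA=1 ATG=4 ATT=2 CTG=2 TTG=2
summary(res$experiment$model)
#> uORF detection regression: n = 84  R-squared = 0.8989
#> Intercept: 0.3016
#> Standardized feature weights (by magnitude):
#>           feature     weight
#>   start_count_log  0.3281...
#>  inframe_fraction  0.2676...
#>  ...
evaluate_calls(res$experiment$calls, res$truth)
#> $sensitivity [1] 1      $fdr [1] 0      $n_calls [1] 12   $n_truth [1] 12
head(res$experiment$calls[, c("gene_id", "start_pos", "start_codon", "score", "q_value")])
#>   gene_id start_pos start_codon     score     q_value
#> 1 gene001        56         CTG 0.7446109 0.013636364
#> 2 gene002         4         ATG 1.1207596 0.007142857
#> ...
```

The 30-gene simulation plants one uORF in half the genes at 5× leader
background density; the experiment enumerates 84 candidate start codons
(planted plus random decoys), fits the detection regression (start-codon
P-site count and in-frame fraction carry the largest weights, as they
should), and calls 12 uORFs at the 5% FDR — here recovering all 12 planted
uORFs with no false calls. `run_uorfseqr(cfg, out_dir)` runs the same thing
end-to-end over two species with end-seq peak calling and homolog
classification, writing TSV tables and a JSON run manifest.

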