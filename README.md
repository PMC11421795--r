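# cmipage

Gene-set enrichment analysis with conditional mutual information and
annotation-bias correction.

## What it does and for whom

Transcriptomics analyses routinely end with the question: *which regulatory
programs — pathways, transcription-factor / RNA-binding-protein / miRNA
regulons — explain the observed differential expression?* Enrichment tools
answer it by testing whether a set's member genes are distributed
non-randomly across a per-gene differential score. But gene-set annotations
are biased: the number of sets a gene belongs to (its **membership degree**)
follows a power law, inflated for well-studied and highly abundant genes, so
promiscuous genes carry less evidence about any particular regulon than
specific ones.

`cmipage` is for analysts of bulk or single-cell differential expression (or
transcript-stability) profiles who want enrichment calls that are robust to
this bias. It measures the dependence between the binned profile *X* and the
membership indicator *Y* conditional on binned degree *Z*:

```
I(X;Y|Z) = Σ_z p(z) Σ_{x,y} p(x,y|z) log2 [ p(x,y|z) / (p(x|z) p(y|z)) ]
```

with plug-in probabilities from raw bin counts (no smoothing). Significance
comes from a permutation test with early stopping; an information-ratio
filter `I(cand; X | acc) / I(cand; acc) > r` removes redundant sets; per-bin
signed hypergeometric scores (`±log10` of the smaller tail p-value) provide
the familiar enrichment heatmap. Because mutual information detects any
deviation from independence, non-monotonic patterns (dual regulators with
targets at both profile extremes) are captured. Setting
`condition = FALSE` reproduces the unconditioned mutual-information
baseline.

The package also ships the full validation machinery: a synthetic-data
generator with planted truncated-normal signals and promiscuous-gene bias
injection, PR/ROC/DET/FDR benchmarking, robustness sweeps, per-sample
regulon activity scoring, and power-law diagnostics of annotation bias.

## Worked example

Simulate a small dataset with 8 perturbed sets among 40 and analyze it:

```r
library(cmipage)
sim <- simulate_dataset(sim_config(n_genes = 2000, n_sets = 40,
                                   n_perturbed = 8, max_size = 200),
                        seed = 1)
fit <- cmipage(sim$profile, sim$sets, n_perm = 200, seed = 1)
fit
#> Conditional mutual information gene-set enrichment
#>   1715 genes, 40 sets (13 tested, 8 significant, 8 accepted)
#>   bins: 10 expression x 3 degree; alpha 0.01; 200 permutations
#>   accepted sets:
#>      set        cmi     p_value direction
#>  set0002 0.15626704 0.004975124        -1
#>  set0005 0.06392665 0.004975124         1
#>  set0007 0.05498177 0.004975124         1
#>  set0004 0.04531716 0.004975124        -1
#>  set0006 0.04097299 0.004975124        -1
#>  set0008 0.04004054 0.004975124        -1
#>  set0003 0.03996255 0.004975124         1
#>  set0001 0.03392492 0.004975124         1
```

All eight accepted sets are exactly the planted ones (`sim$truth`), each
with the correct direction of deregulation: `cmi` is the conditional mutual
information in bits between membership and the binned profile; `p_value` is
the add-one permutation estimate (the minimum attainable at 200
permutations is 1/201 ≈ 0.005); `direction` is +1 for up-regulated member
genes, −1 for down-regulated. Testing stopped after 13 of 40 sets because
five consecutive insignificant results ended the scan. `plot(fit)` draws
the per-bin enrichment heatmap; `as.data.frame(fit)` returns the full table.

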