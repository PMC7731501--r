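# hzexpr

Downstream analysis of hybrid-zone RNA-seq experiments in which two parental
taxa and their natural hybrids are sampled along a sharp soil (edaphic)
gradient. The package covers the complete post-counting workflow for such a
design and ships synthetic-data generators with known truth, so every stage
can be validated end to end without any external download.

## What it computes

Given a transcripts × samples count matrix with transcript lengths, sample
metadata (taxon ∈ {parentA, parentB, hybrid}, zone), a 14-variable soil
table and a GO annotation, `hzexpr` performs:

1. **Normalization** — TMM scaling factors (trimmed mean of M-values: for
   sample *j* against a reference *r*, `f_j = 2^(Σ w_i M_i / Σ w_i)` over
   transcripts kept after trimming 30% of M-values and 5% of A-values from
   each tail, with inverse-asymptotic-variance weights), effective library
   sizes `N_j f_j`, and `FPKM_ij = 10^9 c_ij / (L_i N_j f_j)`.
2. **Differential expression** — common negative-binomial dispersion φ by
   conditional maximum likelihood (variance = μ + φμ²), an exact
   conditional NB test per transcript (group sums compared conditionally on
   their total, two-sided by the minimum-likelihood rule), BH-FDR, and the
   DET call *q* ≤ 0.001 and |log2FC| ≥ 5.
3. **Inheritance classification** — each transcript expressed in all three
   pairwise comparisons of a zone is labelled conserved, additive,
   dominant (towards either parent), transgressive (up/down) or ambiguous
   from the decision table over the three DET outcomes.
4. **Gene–environment association** — PCA of the 14 soil variables (PC1 is
   the edaphic predictor), regularized LDA of site groups, and a ridge
   latent factor mixed model `Y = U Vᵀ + X Bᵀ + E` (K latent factors,
   L2 penalty λ on B) with per-transcript z-scores calibrated by the
   genomic inflation factor `λ_GIF = median(z²)/0.4549364`; transcripts
   with calibrated *p* < 0.05 are soil-associated.
5. **GO enrichment** — elim Kolmogorov–Smirnov tests over the GO DAG
   (deepest terms first; genes of significant terms are eliminated from
   their ancestors), followed by Lin semantic-similarity redundancy
   reduction (representatives pairwise similarity ≤ 0.5).

## Worked example

```r
library(hzexpr)
cfg <- sim_config(n_transcripts = 1000, replicates_per_group = 6,
                  mode_fractions = c(conserved = 0.70, additive = 0.06,
                                     dominantA = 0.06, dominantB = 0.06,
                                     transgressive_up = 0.06,
                                     transgressive_down = 0.06),
                  effect_log2fc = 6, dispersion = 0.1, seed = 1)
sim <- simulate_counts(cfg, zone = "ICA")
md  <- sim$metadata
grp <- function(t) md$sample[md$taxon == t]
de_ab <- run_exact_de(sim$counts,
                      comparison_spec(grp("parentA"), grp("parentB"),
                                      "parentA vs parentB in ICA"))
print(de_ab)
#> parentA vs parentB in ICA: 1000 expressed, 180 DETs (18.00%), up in A 90 / up in B 90

de_ah <- run_exact_de(sim$counts, comparison_spec(grp("parentA"), grp("hybrid"), "A vs H"))
de_bh <- run_exact_de(sim$counts, comparison_spec(grp("parentB"), grp("hybrid"), "B vs H"))
cls <- classify_zone(de_ab, de_ah, de_bh)
print(cls$summary)
#>                 mode   n
#> 1          conserved 700
#> 2           additive  60
#> 3          dominantA  62
#> 4          dominantB  60
#> 5   transgressive_up  60
#> 6 transgressive_down  58
#> 7          ambiguous   0
```

The 18.00% is the DET rate among the 1000 expressed transcripts: 30% of
transcripts have truly different parental means, of which the 6% with
hybrid-specific (transgressive) patterns leave the parents equal, so about
180 transcripts pass both the FDR and the 2^5 fold-change gates. Matching
the per-transcript calls against the generator's truth recovers 99.8% of
the planted modes.

The same stages run from the command line via the wrapper in
`inst/scripts/hzexpr` (`simulate`, `compare`, `inherit`, `associate`,
`all`), with a YAML config plus `--seed/--outdir/--zone/...` overrides.

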