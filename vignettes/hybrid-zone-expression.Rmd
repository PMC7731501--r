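---
title: "Methods: hybrid-zone expression inheritance and edaphic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid-zone expression inheritance and edaphic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzexpr)
```

`hzexpr` analyses RNA-seq counts from a hybrid-zone design: two parental
taxa occupying contrasting soil microhabitats, their hybrids spread across
both, and a table of soil geochemistry at every sampled site. This vignette
documents the statistical model behind each stage, the tunable parameters,
the synthetic-data generators used to validate the pipeline, and the
numerical choices and limitations a user should know about.

## Normalization

Library composition is corrected by TMM (trimmed mean of M-values). For
sample $j$ against a reference sample $r$ (the sample whose 75th-percentile
count-per-million is closest to the across-sample mean), transcripts with a
zero count in either member of the pair are dropped, and for the rest
$M_i = \log_2(p_{ij}/p_{ir})$ and $A_i = \tfrac12\log_2(p_{ij} p_{ir})$
where $p_{ij} = c_{ij}/N_j$ is the count proportion. After trimming 30% of
the $M$ distribution and 5% of the $A$ distribution from each tail
(`trim_m`, `trim_a`), the factor is
$f_j = 2^{\sum_i M_i/w_i \,/\, \sum_i 1/w_i}$ with the asymptotic variance
$w_i = (1-p_{ij})/p_{ij} + (1-p_{ir})/p_{ir}$, and factors are rescaled to
geometric mean 1.

One numerical choice deserves emphasis: the variance weights are computed on
the *proportion* scale rather than from raw counts. The two weightings are
proportional whenever library sizes are equal, but raw-count weights make
the estimated factor drift by order $10^{-3}$ when a library is resequenced
to a different depth, whereas proportion-scale weights make $f_j$ exactly
invariant to rescaling any sample's counts — a property the package asserts
in its tests. On unequal libraries the two versions differ slightly; the
test suite cross-checks against the weighted implementation in `edgeR` at a
correspondingly loose tolerance.

FPKM is computed against the *effective* library size
$\mathrm{FPKM}_{ij} = 10^9 c_{ij}/(L_i N_j f_j)$, and downstream stages use
$\log_2(\mathrm{FPKM}+1)$ (pseudocount configurable; row-centering optional
and used only for display-style matrices).

## Differential expression

Counts in the two groups of a comparison are quantile-adjusted to a common
library size (expectation-matching rescaling to the geometric mean of the
effective sizes, rounded to integers), summed within groups, and compared by
an exact conditional negative-binomial test. A common dispersion $\varphi$
(variance $\mu + \varphi\mu^2$) is estimated by maximizing the conditional
log-likelihood summed over transcripts and groups on
$\varphi \in [10^{-6}, 10]$ (1-D bounded search, tolerance $10^{-4}$).
No tagwise empirical-Bayes shrinkage is applied: a single $\varphi$ keeps
the test exactly enumerable, and every p-value the package produces can be
(and in the tests, is) verified against a brute-force enumeration of all
splits of the conditional total.

Conditional on $s = y_A + y_B$, group sums are independent NB variables
(sums of $n$ i.i.d. NB($\mu,\varphi$) draws are NB($n\mu, \varphi/n$)); the
two-sided p-value sums the probabilities of all splits no more likely than
the observed one (minimum-likelihood rule; tail-doubling available via
`method = "doubletail"`). At $\varphi = 0$ this reduces to the exact
binomial test. log2 fold changes use group sums with a 0.5 pseudocount, so
swapping group labels negates the fold change and leaves p-values unchanged
exactly.

A transcript is *expressed* in a comparison when its total raw count
reaches `min_total_count` (default 10), and is a DET when $q \le$ `fdr_max`
(default 0.001, BH step-up) and $|\log_2\mathrm{FC}| \ge$ `min_abs_log2fc`
(default 5, i.e. a $2^5$-fold difference). The fold-change gate is unusually
stringent; it is kept as the default deliberately and both thresholds are
plain arguments. Percentages in summary tables are rounded half-up to two
decimals.

## Inheritance classification

Within a zone, three comparisons are run (parents; each parent vs the
hybrids) and each transcript expressed in all three is classified:

| hybrid vs A | hybrid vs B | parents | mode |
|---|---|---|---|
| n.s. | n.s. | n.s. | conserved |
| higher | higher | any | transgressive up |
| lower | lower | any | transgressive down |
| higher/lower | lower/higher | any | additive |
| n.s. | different | any | dominant towards A |
| different | n.s. | any | dominant towards B |
| n.s. | n.s. | different | ambiguous |

"Conserved" demands no significant difference in *any* of the three
comparisons. The leftover pattern — parents differ while the hybrid is
indistinguishable from both — is reported as an explicit `ambiguous` class
rather than silently merged, so mode counts always sum to the number of
eligible transcripts. Significance here is the full DET call (FDR *and*
fold-change gates), since classification downstream of DET calling is how
such tables are produced in practice. Because additive calls require both
hybrid-vs-parent tests to be individually significant, additive patterns
whose true effects sit below the gates are systematically called conserved
or dominant — which is why stringent thresholds can yield zero additive
calls even when intermediate inheritance exists; the tests assert this
monotonicity rather than treating it as a defect.

## Soil ordination and the edaphic predictor

The 14 soil variables (pH, OM, CEC, SB, BSP, ASP, PA, P, K, Ca, Na, S, Al,
Mg) are standardized and decomposed by PCA; PC1 is the edaphic predictor.
Its sign is fixed so the Na loading is non-negative, making the predictor
orientation reproducible (nothing else depends on the convention). LDA
directions maximize the between/within variance ratio via the generalized
eigenproblem $W^{-1}B$; because soil designs routinely have fewer sites
than variables, $W$ is ridge-regularized with
$\varepsilon = 10^{-8}\,\mathrm{tr}(W)/p$ (escalated if still
ill-conditioned), and coefficients are scaled to unit pooled within-group
variance. At most $g-1$ discriminants are returned. With exactly zero
between-group scatter the eigenvalues vanish; with sampled sites they are
positive at order $p/n$ even under identical population means, which is the
expected behaviour of sample LDA, not a defect.

## Latent factor mixed model and calibration

Expression (samples × transcripts $\log_2(\mathrm{FPKM}+1)$, by default
restricted to the zone's DETs) is modelled as
$Y = U V^\top + X B^\top + E$ with $K$ latent confounder axes and ridge
penalty $\lambda\|B\|_F^2$ ($\lambda = 10^{-5}$ by default; $K$ is a user
choice — a scree of PCA variance proportions can inform it, but the package
never auto-selects). Profiling $B$ out of the objective leaves
$\|(I-P_\lambda)^{1/2}(Y - UV^\top)\|_F^2$ with
$P_\lambda = X(X^\top X+\lambda I)^{-1}X^\top$, whose rank-$K$ minimizer is
a truncated SVD in the transformed sample space. The solver therefore
computes the *global* optimum in closed form and then applies exact block
updates (SVD for $(U,V)$ given $B$; per-transcript ridge for $B$ given
$(U,V)$) until the relative objective change falls below `tol`; the stored
objective trace is non-increasing by construction. Plain block-coordinate
descent from a zero start was found to stall at stationary points a few
parts in $10^6$ above the optimum, which is why the closed form is used for
initialization.

Association tests are OLS of each transcript on $[1, X, U]$; the z-score is
the t-statistic of the $X$ coefficient with a normal approximation for the
raw p-value. Calibration divides $z^2$ by
$\lambda_{GIF} = \mathrm{median}(z^2)/0.4549364$ (the $\chi^2_1$ median, to
7 digits) and takes the upper $\chi^2_1$ tail; transcripts with calibrated
$p < 0.05$ are declared soil-associated. Genomic-inflation rescaling is a
single-scalar correction: it restores null uniformity when residual
confounding inflates all z-scores by a roughly common factor (mild
unmodeled structure, $\lambda_{GIF} \lesssim 2.5$ in our validation runs),
but cannot repair the heavy-tailed z mixtures produced by strong unmodeled
confounders. The package's calibration checks therefore plant three latent
axes with per-transcript loadings of s.d. 0.2 (log2 scale) and fit $K = 2$;
users facing larger inflation factors should increase $K$ rather than trust
the rescaling.

## GO enrichment and redundancy reduction

Annotations are propagated by the true-path rule, and information content
is $IC(t) = -\log(n_t/n_{root})$ from the *input* annotation corpus (not an
external database), so runs are self-contained. Enrichment uses gene scores
in $[0,1]$ (typically raw or calibrated p-values; smaller = more
interesting) and processes terms in decreasing depth order. Each term is
tested by a one-sided two-sample Kolmogorov–Smirnov test of its currently
retained genes against all other scored genes, with the alternative that
term genes' scores are stochastically smaller; if the p-value falls below
`elim_cutoff` (default 0.01; the reporting threshold is a separate
$\alpha = 0.05$), the term's genes are eliminated from all its ancestors
before those are tested. `elim_cutoff = 0` reproduces the classic test
exactly. Terms with fewer than `min_genes` (default 5) scored genes are
skipped, since smaller KS tests are uninformative. Note that elim p-values
are *not* guaranteed to be larger than classic ones; the meaningful
guarantees — elimination flows only upward, and signal-free scores give
conservative, never anti-conservative, p-values — are asserted in the test
suite. The discreteness of exact small-sample KS p-values makes the null
slightly conservative rather than exactly uniform.

Redundancy reduction uses Lin similarity
$\mathrm{sim}(t_1,t_2) = 2\,IC(\mathrm{MICA})/(IC(t_1)+IC(t_2))$, with
ancestor closures including the terms themselves. Lin similarity was chosen
among the common IC-based measures because it is self-normalizing to
$[0,1]$, which makes the 0.5 redundancy threshold directly interpretable. A
greedy sweep in ascending p-value order (ties: larger IC, then term id)
keeps a term iff its similarity to every kept representative is at most
`sim_threshold` (default 0.5); the tie-break makes the output fully
deterministic.

## Synthetic data: what it emulates and what it does not

`simulate_counts()` draws NB counts (variance $\mu + \varphi\mu^2$) for the
three groups with a configurable mixture of inheritance modes. With
$e$ = `effect_log2fc`, the log2 group offsets are: additive
$(+e, -e, 0)$; dominant $(\pm e/2, \mp e/2, \text{matching one parent})$;
transgressive $(0, 0, \pm e)$; conserved $(0,0,0)$. The parental sign
alternates per transcript within each mode so neither parent accumulates
all up-regulation — otherwise a compositional bias would be baked into the
TMM validation. Library-size factors are log-uniform in `lib_size_range`
(counts are independent NB per transcript scaled by the factor, which is
simpler than multinomial sampling and adequate for testing normalization);
latent confounders contribute $U w^\top$ on the log2 scale; a uniform
$[-1,1]$ per-sample predictor adds `env_effect_size` log2 units per unit
for the flagged `env_effect_fraction` of transcripts. Mode counts are
`round(fraction × n)` with the remainder assigned to conserved. Sample-level
quantities come from one seeded stream; per-transcript draws use fixed seed
offsets so extending the transcript set does not reshuffle earlier ones.

Defaults describe a realistic field design: 4 replicates per group
(configurable — real hybrid-zone samplings run 3–6), a base mean of 100
counts (a moderately expressed transcript; also the regime where the
discrete exact test is effectively continuous, which the null-uniformity
checks assume), dispersion 0.1, and a true effect of $2^6$ so that planted
signals clear the $2^5$ DET gate with margin. `simulate_soil()` draws
multivariate-normal sites around group means following a dune profile
(higher pH and Na) vs a flooded-swale profile (more organic matter, acidity
and Al) with hybrids intermediate; these means are synthetic, chosen for
plausibility, and carry no measured values. `simulate_go()` builds a random
single-rooted DAG of bounded depth, and `simulate_gene_scores()` plants
enrichment by giving a term's genes Beta(1, strength) scores.

The generators do not emulate read-level error, isoform structure,
transcript-length biases in counting, tagwise dispersion variation,
correlated soil covariance across groups, or spatial autocorrelation of
sites. Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not robustness to every artefact of
field RNA-seq data.

## Problem sizes and determinism

The validation suite runs the null type-I check on 2,000 transcripts with
4+4 replicates at $\varphi = 0.2$; inheritance recovery on 2,000
transcripts, 6 replicates per group, $\varphi = 0.1$, effect $2^6$ (≥90%
of planted modes recovered, with parent-label swaps exchanging the dominant
classes exactly); LFMM solver checks on 8×30 instances against a 20-restart
L-BFGS oracle; and calibration/power checks on 24 samples × 2,000
transcripts. These sizes were chosen so the entire suite runs in about a
minute while keeping every Monte-Carlo margin comfortable. All pipeline
outputs are plain TSV/CSV/JSON, logs carry no timestamps, and a fixed seed
makes reruns byte-identical.

## Known limitations

* Common (not tagwise) dispersion; strongly gene-specific overdispersion
  will make the exact test anticonservative for the noisiest genes.
* The exact test enumerates all splits of the conditional total; group
  sums in the millions would be slow (the intended scale is thousands).
* Genomic-inflation calibration is a one-parameter correction (see above).
* LDA coefficients under heavy ridge regularization ($n \ll p$) separate
  the training groups but are not generalization-optimal.
* The elim procedure follows a fixed depth order; ties between same-depth
  sibling terms are processed in term-id order, which can matter when two
  siblings share most of their genes.
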