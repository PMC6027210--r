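---
title: "Methods: sex-biased expression, tissue specificity and rate of evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased expression, tissue specificity and rate of evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranabias)
```

# The analysis problem

In species with homomorphic sex chromosomes, sexual dimorphism must be built
largely from differential expression of a shared genome. Given RNA-seq counts
from several developmental stages (Gosner 23 through 46) and adult tissues
(brain, liver, gonad) of genetically sexed XX and XY individuals, the package
answers four linked questions: which genes are sex-biased in which
stage/tissue; how tissue-specific is each gene's expression; whether
sex-biased genes concentrate on the sex chromosomes (here chromosomes 1 and
2); and how sex bias and specificity relate to the rate of protein evolution
(dN/dS against an outgroup).

# Sex-bias calling

## Filtering and normalization

Within one stage/tissue a gene is *expressed* when its mean log2 CPM across
the class's samples exceeds 0 and its CPM exceeds 1 in at least half of the
samples of each genetic sex. CPM here is computed on raw library sizes:
filtering precedes normalization, so the retained gene set does not depend on
the scaling factors it will later feed. A gene with a zero count in any
sample has mean log2 CPM of negative infinity and is dropped — deliberately
strict, since the downstream exact test conditions on totals and is most
interpretable on genes seen in every library.

Between-sample scaling uses the trimmed mean of M-values: gene-wise
log-ratios against a reference sample (the one whose CPM upper quartile is
closest to the mean upper quartile), two-sided trimming of 30% of the
log-ratios and 5% of the abundances, inverse asymptotic binomial variance
weights, and rescaling of the factors to geometric mean 1. The test suite
checks this implementation against edgeR's `calcNormFactors` to three
decimals on simulated libraries.

## The test

The package tests XY versus XX samples with a conditional exact-style
negative-binomial test. Counts are scaled to a common effective depth (the
geometric mean of TMM-adjusted library sizes) and rounded; under a common
dispersion $\phi$ the group-A sum conditioned on a gene's total follows a
negative hypergeometric (Dirichlet-multinomial) law with shapes
$n_A/\phi, n_B/\phi$, free of the unknown gene mean. The two-sided p-value
sums the probabilities of all outcomes no more likely than the observed one;
totals above $2\times10^5$ switch to a normal approximation of the same
conditional law with continuity correction. The common dispersion is the
across-genes moment ratio $\hat\phi = \sum_g (v_g - m_g)/\sum_g m_g^2$
(within-group means and variances, df-weighted), floored at $10^{-4}$.
Because the dispersion is shared across thousands of genes its estimation
error is negligible, and the acceptance suite verifies type-I error within
three binomial standard deviations of the nominal 5% on a 5000-gene null.

A gene is *sex-biased* when the Benjamini–Hochberg q-value is below 0.05 and
|log2 FC| ≥ 1, where log2 FC = log2((mean male CPM + 0.5)/(mean female CPM +
0.5)); the 0.5 prior avoids division by zero and is standard practice.
Fold-change categories follow the labels low (fold change exactly 2), mild
(2–4), high (4–8) and very high (≥ 8); since the calling gate already
requires fold change ≥ 2, sub-2 fold changes are simply unbiased. BH
adjustment delegates to `stats::p.adjust`; the brute-force step-up
construction lives in the test suite as its oracle.

# Tau tissue specificity

Expression is pooled into 11 classes: G23, G27, G31, brain and liver pooled
over sexes (gonadal differentiation has not yet produced sex differences in
the early stages, and the somatic tissues are pooled to measure the tissue
signal rather than the sex signal), plus female/male G43, female/male G46,
testis and ovary kept sex-limited. Each class value is the mean TPM of its
samples, and

$$\tau = \frac{\sum_{i=1}^{N} \left[1 - \log(TPM_i)/\log(TPM_{max})\right]}{N - 1}.$$

Two conventions are not fixed by the formula and are set here explicitly:
TPM values below 1 are floored to 1 before the logarithm (otherwise negative
logs make the index escape [0,1] and a zero class is undefined), and the log
base is irrelevant because only the ratio of logs enters. Genes with no
class above 1 TPM have undefined Tau, are flagged `NA`, and are excluded
from specificity analyses. Genes with τ > 0.8 are called tissue-specific
(τ > 0.9 reported as a stricter alternative).

The bias–specificity association is a Spearman rank correlation between
|log2 FC| and τ, run only in classes with at least 100 sex-biased genes.
The absolute value is used because the association of interest is between
the *magnitude* of bias and specificity regardless of direction — tissues
whose dominant direction differs would otherwise flip the sign of the
correlation; `signed = TRUE` gives the literal signed-ratio variant.

# Bias structure and turnover

Directional excess in a class is a one-degree chi-square against 50:50
without continuity correction, applied at the FDR-only threshold and at
cumulative fold-change cut-offs (≥2, ≥4, ≥8). The driver analysis bins
biased genes at signed log2 FC thresholds ±1, ±3, ±5, ±7 (bins nest) and
compares per-gene per-sex mean log2 RPKM between successive bins and between
sexes, by two-sided Wilcoxon rank-sum tests; whether gene-level means or
sample-level values should be compared is not fixed by the design, and
gene-level means were chosen as the unit of replication that matches the
binning. Genes with zero RPKM in one sex receive one tenth of the minimum
positive RPKM of the matrix (an idempotent substitution), so sex-specific
genes enter the extreme bins as extreme sex-biased genes rather than
disappearing. Comparisons where a bin's mean log2 RPKM is negative (raw
RPKM below 1) are flagged uninterpretable.

Turnover is counted among genes sex-biased in *both* classes of a pair:
a gene biased in only one class is neither shared nor a turnover. Pairs
qualify for reporting when they share strictly more than 35 biased genes.
Shared genes partition into consistently male-biased, consistently
female-biased, and turnover; dN/dS and τ comparisons between these classes
use two-sided Wilcoxon tests with raw (uncorrected) p-values over the three
pairs.

# Chromosomal context

Ortholog assignment is reciprocal-best-hit: the best hit per query is the
lowest e-value with ties broken by bitscore and then subject id (making the
matching deterministic and row-order invariant), and a pair is accepted only
if reciprocal with e-value < 1e-10, alignment covering at least half of both
query and subject, and identity ≥ 40%. The hit format is BLAST outfmt 6
extended with `qlen` and `slen`, which the overlap rule requires.

Enrichment per chromosome is a permutation test: the chromosome's assigned
gene count is drawn without replacement from all assigned genes $10^4$
times; the one-sided p-value is $(1 + \#\{draws \ge obs\})/(1 + n_{perm})$
(the plus-one correction keeps Monte-Carlo p-values away from zero), with
counts of male- and female-biased genes evaluated separately against the
same draws, one-sided toward excess for each direction. Bonferroni corrects
within the family of chromosomes × directions (20 tests per class). On small
instances the permutation p agrees with the exact hypergeometric tail, which
the tests exploit as an oracle. Sliding windows are step-1 rolling means
(via zoo) over exactly 40 genes ordered by position, never spanning
chromosome boundaries, with the window's center position the mean position
of its members.

# Molecular evolution

Pairwise dN/dS uses Nei–Gojobori (1986) counting: per-codon synonymous site
fractions from the universal code averaged over the two sequences (changes
producing stop codons count as nonsynonymous); observed differences at
codons differing at several positions are averaged over all substitution
orderings that avoid stop codons, equally weighted; codon pairs whose every
pathway crosses a stop are skipped and counted in `skipped_codons` (and
excluded from the site totals, so sites remain consistent with the analyzed
codons). Proportions are Jukes–Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined at $p \ge 0.75$
(record flagged invalid); ω = dN/dS is `NA` when dS = 0. This counting
estimator was chosen over a maximum-likelihood codon model because it is
fully self-contained and oracle-checkable: the test suite re-derives every
site and difference count with an independent brute-force pathway
enumeration and requires agreement to $10^{-9}$, and estimates on simulated
pairs must recover the generating ω. Its known biases (no
transition/transversion weighting, no codon-frequency correction) are
acceptable here because all downstream use is comparative across gene
groups estimated with the same method.

The rate model is ordinary least squares of $\sqrt{dN/dS}$ on sex-bias
class × τ. Sex bias enters as a three-level factor (unbiased reference) by
default — the natural coding when calls are categorical — with a
`continuous = TRUE` option for the log2 FC covariate. Drop-term F-tests
respect marginality: the interaction against the full model, then each main
effect against the additive model.

# The synthetic-data generator

`simulate_expression()` emulates the study design: 8 stage/tissue classes ×
2 genetic sexes × 4 replicates (64 libraries — the real design used 61
libraries across comparable cells), log-normal gene abundances (log-mean
log(100), log-sd 1.2, typical of bulk RNA-seq after filtering), a common NB
dispersion of 0.1 (mid-range for bulk tissue replicates), and log-normal
library depths (log-sd 0.15). Per-class biased fractions default to values
mirroring the published proportions of tested genes (gonad 0.25, G46 0.15,
G43/brain/liver 0.02, early stages 0.005); each biased gene is biased in
exactly one class with |log2 FC| uniform on [1, 4], the effect split
symmetrically ($2^{\pm lfc/2}$) so the unbiased mean is the geometric
midpoint, and 5% of biased genes are fully sex-specific (mean 0 in one
sex). Chromosomes are 10 equal 100-Mb units with uniform positions; a
`sexchrom_enrichment` odds multiplier places biased genes preferentially on
chromosomes 1–2. `simulate_hits()` gives each gene a reciprocal best pair
meeting all acceptance thresholds with probability 0.9, plus sub-threshold
and secondary decoys, recording the exact truth set. `simulate_orthologs()`
evolves stop-free codon sequences along two branches, accepting synonymous
proposals always and nonsynonymous ones with probability ω; divergence
implying $p_S \ge 0.75$ is rejected up front as uncorrectable.

What the generator deliberately does not emulate: per-gene dispersion
heterogeneity, correlated expression between classes, isoforms and mapping
ambiguity, GC/length biases, and genes biased in more than one class.
Passing recovery tests therefore demonstrates that the pipeline's inference
machinery is correct and calibrated under its own assumptions, not that
those assumptions capture every property of real frog data.

# Problem sizes and numerical choices in the checks

The recovery and calibration checks run at sizes chosen to finish quickly on
one CPU while leaving comfortable statistical margins: 5000 genes for the
null-calibration of the exact test; 2000 genes at 4 replicates/sex for
power (≥ 80% required at |log2 FC| ≥ 2; observed ≈ 93%, with the shortfall
from true positives being entirely sex-specific genes that the expression
filter removes) and observed FDR (≤ 10% required, observed ≈ 1%);
3000 genes × 10 seeds with enrichment odds 5 for sex-chromosome detection
(the published analysis had 11,383 assigned orthologs, so 3000 is a
desk-scale stand-in); 12 pairs × 300 codons per ω for dN/dS recovery; and
300 observations × 20 replicates for the rate-model term separation.
Permutation-null calibration uses the randomized-tail transform
$u = (\#\{null > obs\} + U(1 + \#\{null = obs\}))/(1 + n_{perm})$, which is
exactly uniform when the null machinery is correct, making a
Kolmogorov–Smirnov check valid despite the discreteness of count data.

# Known limitations

- The exact-style test assumes a single common dispersion; strongly
  heteroskedastic genes would be better served by tagwise shrinkage, which
  is out of scope.
- Rounding counts to a common depth is a simplification of quantile
  adjustment; at depth ratios within ±50% its effect is negligible (the
  calibration test covers this regime).
- NG86 undercounts synonymous changes when transition/transversion bias is
  strong; comparisons across gene groups remain valid, absolute ω values
  carry the usual counting-method caveat.
- The strict expression filter excludes fully sex-specific genes from
  bias *testing*; they re-enter the driver analysis through the pseudo-count
  route, which is why that analysis exists.
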