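# ranabias

Tools for studying the dynamics of **sex-biased gene expression** across
development and adult tissues in species with homomorphic (undifferentiated)
sex chromosomes, as in the common frog. The package is aimed at
evolutionary-genomics researchers who have a gene × sample count matrix from
several developmental stages (Gosner stages G23–G46) and adult tissues
(brain, liver, gonad) for genetically sexed (XX/XY) individuals, and who want
to ask: which genes are expressed differently between the sexes, where and
when does that bias arise and switch direction, is it concentrated on the sex
chromosomes, and how does it relate to tissue specificity and protein
evolutionary rate?

## What it computes

- **Sex-bias calling.** Per stage/tissue, genes are filtered for expression
  (mean log2 CPM > 0 and CPM > 1 in at least half the samples of each genetic
  sex), libraries are scaled by the trimmed mean of M-values (TMM), and XY vs
  XX samples are compared with a conditional negative-binomial exact-style
  test with a moment-estimated common dispersion. A gene is *sex-biased* when
  the Benjamini–Hochberg FDR is below 0.05 **and** |log2 FC| ≥ 1, with
  fold-change categories low/mild/high/very-high (2, 2–4, 4–8, >8).
- **Tissue specificity.** The Tau index over the 11 pooled stage/tissue
  expression classes,

  τ = Σᵢ [1 − log(TPMᵢ)/log(TPMmax)] / (N − 1),

  with sub-1 TPM values floored to 1; τ = 0 means uniform expression, τ = 1
  a single expressing class, and τ > 0.8 flags a tissue-specific gene.
- **Bias structure and turnover.** Directional-excess chi-square tests
  across fold-change thresholds, expression-driver binning (which sex's
  expression change produces the bias, with sex-specific genes kept via a
  min-RPKM/10 pseudo-count), and direction-turnover accounting between
  tissue pairs sharing > 35 sex-biased genes.
- **Chromosomal context.** Reciprocal-best-hit ortholog assignment
  (e-value < 1e-10, ≥ 50% overlap of both sequences, ≥ 40% identity),
  permutation tests (10⁴ draws, Bonferroni-corrected) for enrichment of
  male- or female-biased genes per chromosome, Wilcoxon tests of the log2
  male:female ratio on sex chromosomes (1 and 2) vs autosomes, and 40-gene
  sliding-window scans.
- **Molecular evolution.** Pairwise dN/dS by Nei–Gojobori (1986) counting
  with Jukes–Cantor correction, Wilcoxon group comparisons, and linear
  models of √(dN/dS) on sex bias × Tau with drop-term F-tests.
- **Synthetic data.** A fully seeded generator emulating the study design —
  negative-binomial counts with implanted sex-biased fractions per tissue, a
  10-chromosome map with optional sex-chromosome enrichment, reciprocal
  homology hits with decoys, and codon pairs evolved at a known ω — so every
  stage is testable against ground truth.

## Worked example

```r
library(ranabias)

cfg <- sim_config(n_genes = 1000, seed = 42)
sim <- simulate_expression(cfg)

gonad <- call_sex_bias(sim$counts, sim$samples, "gonad")
table(gonad$direction)
#> female   male   none
#>    128    113    734

tpm  <- tpm_matrix(sim$counts$counts, sim$counts$lengths)
taus <- tau_table(pool_profiles(tpm, sim$samples))
spearman_bias_tau(gonad, taus)$rho
#> 0.436
```

Of 975 genes passing the expression filter in the gonad, 241 are called
sex-biased (128 female-, 113 male-biased) — recovering the simulated 25%
biased fraction — and the magnitude of sex bias correlates positively with
Tau (Spearman ρ = 0.436), the same qualitative pattern reported for real
gonadal data. `run_pipeline(config)` (or
`Rscript inst/cli/ranabias.R run --config run.yaml`) chains all stages and
writes one TSV per stage plus a JSON manifest.

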