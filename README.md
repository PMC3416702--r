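# tissuespec

Identify genes specifically or preferentially expressed in one tissue from
unreplicated multi-tissue RNA-seq read counts, and characterize the resulting
gene set by functional enrichment, cross-species conservation, and
between-library concordance. The package grew out of the analysis design used
for the maize silk (stigma) transcriptome — four tissue libraries of 6–7
million unique mapped reads each, no biological replicates — but every stage
is parameterized and works for any tissue panel with the same shape of data.

## What it computes

For a genes × tissues matrix of unique-mapped read counts *C* with library
sizes *N* (total unique mapped reads) and longest-transcript gene lengths *L*
(bp):

- **RPKM normalization** — `RPKM = 10⁹ · C / (N · L)`.
- **Presence filter** — a gene is expressed in a tissue when
  `10⁶ · C / N ≥ 4` reads per million (boundary inclusive); presence
  patterns across tissues are summarized as a Venn partition.
- **Specific genes** — expressed in the focal tissue and nowhere else.
- **Preferential genes** — the Audic–Claverie exact test compares the focal
  library against each other library. Conditional on `x` reads in library 1,
  the count `y` in library 2 under equal underlying rates follows
  `p(y|x) = (N₂/N₁)^y (x+y)! / (x! y! (1+N₂/N₁)^(x+y+1))`, the negative
  binomial law with size `x+1` and success probability `N₁/(N₁+N₂)`. A gene
  is preferential when, in **every** focal-vs-other comparison, fold change
  ≥ 2, p < 10⁻⁵ and Benjamini–Hochberg FDR < 10⁻⁵ (all configurable).
- **Enrichment** — one-tailed hypergeometric (Fisher exact) term
  over-representation `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)` with step-up
  FDR, plus PAGE gene-set z-scores `Z = (S_m − μ)√m / δ`.
- **Homology partition** — best-hit selection from BLAST-style tabular hits
  (lowest E-value ≤ 10⁻¹⁰, ties by bitscore then subject id) against two
  other species, and partition of the focal set into conserved-in-both /
  one-only / distinct subsets with count and percentage summaries.
- **Concordance** — Pearson correlations between libraries on clamped
  `max(0, log₂ RPKM)` values and Spearman correlations across platforms.
- **Synthetic data** — a generator that plants tissue-specific and
  tissue-preferential genes under a Poisson or negative-binomial count model
  (plus hit tables and term annotations with planted enrichment), so the
  whole pipeline is testable without sequencing data.

## Worked example

Simulate the study design at reduced size (2,000 genes, 100 planted specific
and 100 planted preferential genes at fold 8) and run every stage:

```r
library(tissuespec)
cfg <- list(seed = 42, out_dir = tempfile(),
            sim = list(n_genes = 2000, n_specific = 100,
                       n_preferential = 100, preferential_fold = 8))
run <- run_pipeline(cfg)
print(run)
#> pipeline run (focal tissue: MS )
#>   expressed in MS: 1800
#>   specific: 100
#>   preferential: 100
#>   combined: 200
#>   outputs in: /tmp/...
print(run$manifest$recovery)
#> $specific_sensitivity    [1] 1
#> $specific_false          [1] 0
#> $preferential_sensitivity[1] 1
#> $preferential_fdp        [1] 0
```

All 100 planted specific genes are recovered exactly (no false positives)
and all 100 preferential genes pass the fold/p/FDR conjunction in all three
comparisons. The output directory holds the RPKM table, presence Venn,
specific/preferential/combined gene lists, per-comparison test records,
enrichment and homology tables, the library correlation matrix, and a
`manifest.json` echoing the configuration, seed and row counts; rerunning
with the same config and seed reproduces every file byte for byte.

Individual stages are plain functions:

```r
ac_pvalue(120, 12, 6.5e6, 6.3e6)     # 4.23e-23: 120 vs 12 reads is real
hypergeom_tail(10, 900, 52, 39203)   # 2.56e-07: term enrichment in a query
verify_worked_examples()             # recompute the bundled reference tables
```

A thin command-line wrapper (`inst/cli/tissuespec`) exposes `simulate`,
`run-all --config cfg.yaml` and `verify` for shell use.

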