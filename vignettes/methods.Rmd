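---
title: "Methods: calling tissue-specific and tissue-preferential genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling tissue-specific and tissue-preferential genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

## The problem

A dry stigma — the maize silk is the extreme case — interacts with pollen
through genes expressed in the stigma itself. With one RNA-seq library per
tissue and no biological replicates, the question "which genes does this
tissue use that others do not?" reduces to two calls made from raw counts:
*specific* genes, expressed in the focal tissue and in no other profiled
tissue, and *preferential* genes, expressed significantly higher in the
focal tissue than in every other tissue. This vignette records the models
behind each stage, the parameters that matter, and the design decisions
taken where the published analysis left the choice open.

## Quantification and the presence filter

Counts are unique-mapped reads per gene. Abundance is RPKM,
$10^9 C / (N L)$, with $N$ the *total* unique mapped reads of the library
(metadata, not the column sum — real libraries map reads outside any
particular gene set) and $L$ the length of the gene's longest transcript in
bp. When lengths come from GFF3, a transcript's length is its summed exon
length; whether the original analysis used summed exons or genomic span is
not documented, so summed exon length (standard RPKM practice) is the
default and a precomputed length table can override it. Genes missing from
the length table are a hard error: silently dropping them would corrupt the
background totals that enrichment later depends on.

The presence filter is applied to counts per million mapped reads, not
RPKM, because the upstream rule is stated on reads per million before any
length normalization: a gene is expressed when $10^6 C / N \ge 4$. The
boundary is inclusive — "fewer than four per million are eliminated" retains
exactly four. The filter is monotone in $C$ and antitone in $N$, which the
test suite checks as a property.

## The Audic–Claverie test

For two libraries with sizes $N_1, N_2$ and counts $x, y$ for one gene, the
test conditions on $x$ and asks how surprising $y$ is under equal underlying
rates:

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}.$$

This mass is exactly the negative binomial law with size $x+1$ and success
probability $N_1/(N_1+N_2)$, so tails are evaluated with `pnbinom()` —
overflow-free at library-scale counts. The unit tests verify the identity
against direct log-gamma summation of the mass to machine precision for all
$x, y \le 30$.

Numerical and inferential conventions:

- **Two-sided p-value** — twice the smaller conditional tail, capped at 1.
  Preferentiality is subsequently imposed by the fold-change direction, so
  sidedness barely changes the called set; a one-sided mode
  (`alternative = "greater"`) is available.
- **Symmetry** — the doubled-tail construction is not automatically
  symmetric in the two libraries because the point mass lands in different
  tails depending on which observation is conditioned on. The test therefore
  always conditions on the observation with the larger normalized count
  ($x/N_1$ vs $y/N_2$), which makes
  `ac_pvalue(x, y, n1, n2) == ac_pvalue(y, x, n2, n1)` exact.
- **Monotonicity** — at equal depths, p decreases with $|x - y|$ along any
  fixed total. At unequal depths it is monotone in $|x N_2 - y N_1|$ within
  each direction of deviation, but the two directions interleave
  non-monotonically — an unavoidable discreteness effect of the conditional
  distribution, and the reason the property tests check each direction
  separately.
- **Calibration** — under a Poisson null at equal depth and realistic
  per-gene counts (mean 100 reads, about 15 per million at the emulated
  depths), the empirical type-I error at $\alpha = 0.05$ over $10^4$
  simulated genes sits within three binomial standard errors of nominal.
- **Degenerate input** — $x = y = 0$ at unequal depths gives $p = 0.5$, not
  1: observing zero reads in the deeper library is itself (weak) evidence.

## Preferential calling

A gene is preferential when it is expressed in the focal tissue, is not in
the specific set, and in *every* focal-vs-other comparison passes fold
change $\ge$ `min_fold` (default 2), $p <$ `max_p` (default $10^{-5}$) and
FDR $q <$ `max_fdr` (default $10^{-5}$). Decisions taken where the source
analysis is silent:

- **FDR procedure** — unnamed upstream; Benjamini–Hochberg is the field
  default, Benjamini–Yekutieli by flag.
- **FDR family** — genes expressed in at least one member of the pair,
  mirroring the presence pre-filter ("eliminated from further statistical
  analysis") applied before testing; pooling the three comparisons into one
  family is available by flag (`pool = TRUE`).
- **Fold-change scale** — computed on RPKM, the only stated abundance
  measure, with a denominator floor `epsilon = 1e-3` RPKM so genes absent
  elsewhere get a large finite ratio. The floor is three orders of magnitude
  below any expressed gene's RPKM at these depths, so it never affects genes
  that pass the presence filter.

A second, test-free rule (`call_preferential_fold_only()`) designates a gene
preferential when its abundance strictly exceeds `min_fold` times its
abundance in every other tissue; this is the rule used for comparisons
against external datasets where only abundances are available.

## Enrichment

Singular enrichment over flat term sets: $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, the one-tailed Fisher exact
probability, with terms flagged at $p < 0.001$ and FDR $\le 0.05$. The FDR
default is Benjamini–Yekutieli (the dependency-adjusted procedure used by
the upstream web tool family), with BH by flag. Terms are flat gene sets: no
ontology DAG propagation — the annotation provider's concern, not this
package's. The background universe defaults to every gene in the annotation
file.

PAGE z-scores complement the hypergeometric test for comparing conditions:
for per-gene scores (default usage: log2 fold changes) with global mean
$\mu$ and standard deviation $\delta$, a term of $m$ genes with mean score
$S_m$ gets $Z = (S_m - \mu)\sqrt{m}/\delta$ against the standard normal.
$\delta$ is the sample standard deviation of all scores; a term covering
every gene has $Z = 0$ by construction.

### Reproducibility of the published p-values

The package bundles the 48 contingency rows of the published GO-enrichment
tables (query item $k$, query total $n$, background item $K$, background
total $N = 39{,}203$, printed p-value). Recomputing the exact hypergeometric
tail from these printed inputs reproduces the printed p-values in order of
magnitude but **not** at two significant figures for any row — e.g.
$(k{=}10, n{=}900, K{=}52)$ gives $2.56\times10^{-7}$ against a printed
$2.80\times10^{-7}$, and the deviation grows in the extreme tail
($3.3\times10^{-21}$ vs a printed $1.5\times10^{-17}$). No standard variant
(Fisher two-sided, $\chi^2$ with or without continuity correction, binomial
or Poisson approximations in either sampling direction, query-excluded
background) matches either, and the universe size that would reproduce each
printed value is inconsistent across rows (33,200–39,000, shrinking as p
gets smaller) — the signature of a numerical truncation in the original web
tool's tail summation rather than of a different test. The package
therefore reports the exact tail, validated against enumeration;
`verify_worked_examples()` shows each computed value beside its printed
counterpart rather than asserting agreement. The printed FDR columns are
likewise not asserted: the number of tested terms behind them is not
recoverable.

## Homology

The alignment step itself is out of scope; the module consumes standard
12-column tabular hits. Best-hit selection keeps, per query, the lowest
E-value row, with ties broken by higher bitscore then lexicographically
smallest subject id (a deterministic, order-independent rule). Boundary
semantics follow the published criteria literally: homolog screening uses
$E \le 10^{-10}$ (inclusive); probe assignment uses $E < 10^{-20}$ and
identity $> 0.8$ (both strict) — expressed on the `pident` percent scale as
`min_identity = 80`. Subject identifiers are never normalized implicitly;
a transcript-suffix regex must be supplied explicitly because gene-vs-
transcript id conventions are dataset-specific.

`conservation_partition()` is pure set arithmetic on the best-hit key sets,
checked internally for disjointness and exhaustiveness; the bundled worked
example reproduces the published 1,427 → 923 distinct / 364 rice-only split
and the 213/548 = 38.87% summary. Two published percentages (32.96% and
3.77% of 1,427) are arithmetically inconsistent with their own counts
(471/1427 = 33.01%, 48/1427 = 3.36%) and are not asserted; the summary
reports computed percentages at two decimals. The published "9.8%" for
140/1427 is reported as the two-decimal 9.81.

## Concordance

Between-library correlations use Pearson on $\max(0, \log_2 \mathrm{RPKM})$
— the clamp sets sub-unit RPKMs to zero so low-abundance noise does not
dominate — over the genes expressed in at least one sample (configurable to
all genes; the original choice is not fully specified). Cross-platform
comparisons use Spearman (Pearson on mid-ranks, ties averaged) over shared
genes, absorbing the scale discrepancy between platforms. The published
correlation values depend on the deposited libraries and are validated here
by formula oracles and invariants (duplicate samples correlate at 1,
monotone transforms leave Spearman unchanged) rather than by value.

## The synthetic generator

`simulate_counts()` emulates the study conditions: four tissues (MS focal,
MP/MO/SL comparators), library sizes 6.50, 6.15, 6.76 and 6.30 million
reads (the published depth range was 6,145,170–6,764,608; the two
unpublished depths are round values inside it), 20,000 genes of which 10%
are silent (true negatives for the presence filter), 725 specific and 702
preferential genes by default (the published set sizes), preferential fold
8 — a clearly detectable effect well above the fold-2 calling threshold —
and Poisson counts (`dispersion = 0`), matching the assumption of the
unreplicated exact test; negative-binomial overdispersion
($\mathrm{var} = \mu + \alpha\mu^2$) is available for sensitivity analyses.
Baseline rates are log-normal (meanlog $\log 50$, sdlog 1 on the
reads-per-million scale) — a modelling choice, not a published claim; the
original distribution of expression levels is not described. With
`calibrate_depth = TRUE` the baseline rates are rescaled so expected column
totals match the configured depths; the count table still carries the
*realized* column sums so normalization is self-consistent. Specific genes
get rate zero outside the focal tissue and a floor of 20 reads per million
inside it; gene lengths are uniform on 200–5,000 bp, exercising the RPKM
length correction without claiming biological realism.

What the generator does *not* emulate: read-level error, alignment
ambiguity, isoform structure, batch effects, or correlated expression
between genes. Passing recovery tests therefore demonstrates that the
calling chain is correct under its own assumptions, not that those
assumptions hold for any real library.

Synthetic hit tables plant a designated lowest-E-value subject per matched
query (plus weaker qualifying hits and non-qualifying decoys), and
synthetic annotations plant one term whose membership odds inside a query
set are multiplied by a configurable factor, so enrichment, best-hit and
partition logic are all tested against generator truth.

## Problem sizes and test design

The test suite runs the recovery experiment at 2,000 genes with 100 planted
specific (rate floor 20 per million) and 100 preferential genes at fold 8 —
large enough that expected counts sit far from the presence boundary, so
exact specific recovery is the correct expectation rather than a lucky
draw — and uses $10^4$ gene pairs for null calibration, 500 replicates for
enrichment null uniformity, and full enumeration up to $x, y \le 30$ for
exactness. Every stochastic test fixes its seed; end-to-end runs are
asserted byte-identical under a fixed configuration.

## Limitations

- No replicate-aware or dispersion-moderated testing: the exact test treats
  biological variability as zero beyond Poisson noise, as any unreplicated
  design must. Calls should be read as "library differs", not "biology
  differs", wherever replication is absent.
- Terms are flat sets; annotations with DAG semantics must be propagated
  upstream.
- Best-hit homology is unidirectional per direction and is not orthology
  inference; no synteny, trees, or reciprocal-best requirement.
- TPM and other normalizations are out of scope; RPKM is the only
  abundance measure implemented.
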