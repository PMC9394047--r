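---
title: "Methods: cross-species transcriptome conservation and GWAS enrichment"
author: "orthoconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species transcriptome conservation and GWAS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoconserve)
```

## Scope and data model

`orthoconserve` compares gene expression between two species over their
one-to-one orthologs. Its substrate is a pair of validated
`ExpressionMatrix` objects (genes × samples TPM, per-sample tissue
labels, dense and non-negative), linked by a bijective `OrthologMap`.
Missing TPM cells are rejected rather than imputed: the compendia this
mirrors are dense, and silent imputation would bias every downstream
variance estimate. Annotation TSVs are 1-based inclusive on disk
(GFF-like) and converted to 0-based half-open internally; BED
segmentations are already half-open. Marker tables are sorted to genome
order — chromosomes in the order of the genome-sizes file (or first
appearance), positions ascending — because the cyclical permutation null
is defined along that order.

## Expression conservation

All expression-level testing happens on `log2(TPM + 0.25)`. The +0.25
offset keeps zeros finite (TPM 0 maps to −2) and is used consistently:
the same transform feeds differential expression, variability and the
generator's inverse map `TPM = max(2^x − 0.25, 0)`.

**Between-species differential expression** is an ordinary Welch
two-sample *t*-test per ortholog pair, with `log2fc` the difference of
group means on the log scale and significance at `|log2fc| > log2(1.2)`
and BH FDR < 0.05. Two deliberate choices here:

- We use the plain Welch *t* rather than an empirical-Bayes moderated
  *t*. The load-bearing content is the fold-change and FDR thresholds
  and the −log10 p ranking, not variance shrinkage; at the sample sizes
  this package targets (tens to hundreds per tissue) moderation changes
  little, and the Welch test has an exact, dependency-free definition
  that the test suite can verify against `stats::t.test`.
- The FC > 1.2 threshold is applied on the log2 scale
  (`|log2fc| > log2 1.2`), i.e. to the ratio of geometric means. A
  linear-scale ratio of arithmetic means would be dominated by a few
  high-expression samples; one consistent scale keeps the DE test, the
  tissue-specific test and the generator aligned.

**Tissue-specific expression** is one-vs-rest Welch on the same scale,
flagged only for upregulation (`log2fc > 1.5`, FDR < 0.05).

Degenerate inputs are kept total rather than dropped: two zero-variance
groups with equal means give p = 1; zero variance with unequal means
gives p = the smallest positive double, with the row flagged
`degenerate` and a warning. This keeps the −log10 p ranking defined for
every gene; a flagged extreme beats any finite test statistic, which is
the right outcome for a gene that is constant at different levels in the
two species.

**Summaries.** Per (gene, tissue): median TPM, mean and MAD of log2
expression, CV of linear TPM (n−1 sd / mean, NA at mean 0), and
`expressed = median TPM > 0.1` (strict inequality; a median of exactly
0.1 is not expressed). The MAD is unscaled — no 1.4826 consistency
factor — because only rankings and correlations of MAD are consumed and
a constant factor cancels. **tau** is computed on per-tissue median TPM
without log transform, matching the common tool default of operating on
the vector it is handed; callers wanting log-scale tau can transform
first.

**Rankings and windows.** Rankings are total and deterministic: ties in
the score are broken lexicographically by gene id, undefined scores sink
to the bottom. Decile windows hold `floor(n/10)` genes; the `n mod 10`
lowest-ranked genes are dropped from windows (17,315 orthologs → 1731
per window) but remain eligible for the top/bottom sets, which are cut
directly as `floor(fraction · n)` from each end. Orientation is
metric-dependent and explicit: the top of a DE or variability ranking is
*diverged*, the top of a corCor ranking is *conserved*.

**Tissue clustering** uses 1 − Pearson r distance with complete linkage,
the standard choice for correlation-profile heatmaps; constant profiles
are an error naming the offending tissue.

## Differential variability

For each ortholog pair, `f = s1²/s2²` of log2 expression, referred to
F(n−1, m−1). The test is two-sided (doubling the smaller tail): excess
variability in either species is divergence. Sample sizes are used as
they come — no subsampling to balance n and m; the F reference handles
unequal sizes exactly, at the cost of unequal power in the two
directions, which is immaterial for a two-sided ranking statistic.
Ranking for the conserved/diverged partition uses −log10 FDR (the DE
partition uses −log10 p); both keys are exposed as parameters since the
two conventions coexist in practice.

## Co-expression conservation

corCor uses Spearman correlation inside (robust to per-gene monotone
distortions between platforms and species — this invariance is tested)
and Pearson outside, over background vectors of length exactly n − 1
(the self-correlation is excluded). Spearman ties get average ranks.
Genes constant in either matrix are flagged and excluded from every
background vector, not just their own row. The recommended background
is the genes expressed in the tissue in both species; the function takes
whatever aligned matrices the caller restricts to, so this is a usage
convention rather than a hard-coded filter.

Soft connectivity is `k_i = Σ_j |r_ij|^β` with β = 6 by default — the
customary power for signed-magnitude weighted networks; it is a
parameter because no single β is canonical. Module *detection* is out
of scope: modules arrive as gene sets (from the generator's truth or
from user files), and module conservation is scored by the Pearson
correlation of the two species' connectivity vectors over the module.

## GWAS signal enrichment

`T_sum = Σ b²` over the markers assigned to a gene set; markers are
assigned when they lie within `[start − ext, end + ext]` of any set gene
(1-based inclusive bounds — a marker exactly `ext` bp past the gene end
is included; masks are unions, so overlapping genes never double-count a
marker). The default extension is 50 kb, wide enough to absorb most
cis-regulatory variation.

The null rotates the genome-ordered effect vector by a uniform offset in
1..M−1 (drawn with replacement; offset 0 excluded) against the fixed
mask. Rotating effects against a fixed mask is equivalent to the
genotype-rotation formulation for this statistic and needs no genotype
matrix; it preserves the set's marker count, spacing and the local
correlation of effects, which is what distinguishes it from naive
marker resampling under linkage disequilibrium. The empirical p is
`(1 + #{T_perm ≥ T_obs}) / (n_perm + 1)`: the add-one correction keeps
p ≥ 1/(n_perm+1) (a pure proportion can return an unusable 0 and is
available via `pseudocount = FALSE` for compatibility), and ties count
against significance — the conservative reading of "greater than
observed". Default 10,000 rotations.

Gene-set overlaps use the hypergeometric upper tail
`P(X ≥ k)` = `phyper(k − 1, A, N − A, B, lower.tail = FALSE)`.

## Chromatin-state enrichment

fold = (C/A)/(B/D) per state, with the TSS at the annotated start for +
genes and end for − genes, windows of ±2 kb clamped to chromosome bounds
and merged before counting (B and C count unique bases). Because the
segmentation covers the genome exactly once, Σ A = D and Σ C = B — both
are asserted in the tests — and a state covering the whole genome is
forced to fold 1 by the formula.

## The synthetic-data generator

The generator emulates the *structure* the pipeline must detect, not the
full messiness of real compendia:

- log2-scale expression with per-gene baselines ~ N(3, 1.5²), shared
  tissue effects ~ N(0, 0.5²), residual SD 1.0 — spreads chosen so TPM
  dynamic range and tissue separation resemble bulk RNA-seq after TPM
  normalisation;
- diverged genes: ± `mean_shift_log2` (default 2) in species B, sign
  per gene, since real divergence goes both directions;
- variance-shifted genes (disjoint from diverged by construction): the
  whole centred deviation — module factor plus noise — is scaled by
  √`variance_ratio` in species B, so the realised variance ratio equals
  the parameter exactly rather than being diluted by an unscaled factor
  component;
- co-expression from one latent factor per module,
  `x += λ_g f_m`, `λ_g ~ ±Uniform(0.5, 1)`; scrambled modules redraw λ
  independently in species B, destroying the wiring while preserving
  each gene's margins — the minimal model that makes corCor
  discriminating;
- tissue-specific genes: +4 log2 units in exactly one tissue, both
  species;
- markers: genes tile chromosomes evenly, markers are evenly spaced,
  `b ~ N(0, background_effect_sd²)` with √`enrichment_ratio` inflation
  inside a random enriched gene set;
- segmentation: 200-bp tiling, every base covered exactly once, with one
  state's sampling odds multiplied by `tss_bias` within ±2 kb of TSSs.

Defaults mirror the paired-compendium conditions the package targets:
17,315 orthologs, 20 tissues, 541/243 samples per tissue, 10% diverged,
10% variance-shifted at ratio 4, 20 modules with a quarter scrambled.
One global seed is split into fixed per-generator substreams
(`seed mod 1e5 × 7919 + counter`, counters 1–3), so adding a generator
never shifts an existing stream; runs are bit-reproducible.

What it does **not** emulate: library-size and batch effects, count
noise and mean–variance coupling, heavy-tailed expression, unbalanced
designs, LD between markers, or realistic gene length distributions.
Passing parameter-recovery tests therefore demonstrates that the
statistics detect the structure they claim to detect at realistic effect
sizes — not that real cross-species data will be as clean.

## Problem sizes in the test suite

The suite validates at reduced scale, chosen to exercise every code path
with comfortable statistical margins: parameter recovery uses 600 genes
× 2 tissues × 50 samples per tissue over 10 seeds; corCor ordering 200
genes × 40 samples; F-test calibration 10,000 null genes at n = m = 50;
permutation uniformity 500 independent gene sets at 500 rotations (note
that a Kolmogorov–Smirnov statistic over 500 draws carries sampling
noise of order 0.04 even under perfect uniformity); enrichment power 100
generator seeds. `scripts/acceptance.R` recomputes the same quantities
from scratch under a caller-supplied seed.

## Known limitations

- The Welch test assumes approximate normality of log2 expression within
  groups; strongly zero-inflated genes violate this, and the expressed
  filter (median TPM > 0.1) is the intended guard.
- The F-test is not robust to heavy tails (no Levene/Brown–Forsythe
  alternative is provided); on real data its ranking should be read as
  descriptive.
- corCor on all orthologs mixes expressed and unexpressed genes;
  restrict to a common expressed background for interpretable values.
- The permutation null assumes effects are exchangeable under rotation
  up to local structure; strong genome-scale trends (e.g. per-chromosome
  effect-size gradients) would violate it.
- Heritability partitioning, LD-score regression, fine-mapping, eQTL
  mapping and module detection are deliberately out of scope; their
  outputs are consumed as gene sets or not at all.
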