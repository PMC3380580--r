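---
title: "Methods: gene-body methylation meta-analysis and the accessibility-interference simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-body methylation meta-analysis and the accessibility-interference simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genebody)
```

This vignette documents the models, conventions and design decisions behind
`genebody`, in the spirit of a methods section: what each stage computes,
which choices were genuinely open, and what the simulation-based validation
does and does not establish.

## Coordinates and locus anatomy

All coordinates are 0-based half-open `[start, end)` (the BED convention),
in files and in memory. Interval algebra is delegated to Bioconductor's
IRanges; tables are tibbles throughout.

Transcripts overlapping by at least one base pair on the same chromosome
(and, by default, the same strand) merge transitively into one **gene
locus** spanning the 5'-most to the 3'-most exon. Two conventions here were
open and are worth stating:

* **Strand-aware merging is the default.** Antisense genes overlapping a
  locus on the other strand are biologically distinct, so they stay
  separate; `strand_aware = FALSE` reproduces strand-blind merging for
  comparison. Abutting spans (sharing zero bp) never merge.
* **Overlap is defined on transcript spans**, introns included, not on exon
  overlap — the locus definition is the bounding interval of its members.

From a locus we derive: the **TSS** and **TTS** as single 0-based positions
(5' and 3' ends in transcription orientation); the **gene body**
`[TSS+1 kb, TTS−1 kb)`, empty when the locus is ≤ 2 kb (such genes are
excluded from body statistics — the trim size is a parameter); **introns**
as span minus exon union; flank windows oriented along transcription and
clipped at chromosome ends rather than dropping the gene. Whether flanks
overlapping a neighbouring gene should be clipped is unknowable from first
principles; we do not clip, and CpGs in such windows simply contribute to
both genes' profiles.

One derived convention: the metagene profile extends 5 kb downstream of the
TSS, which reaches past the body boundary. For *scalar* per-gene TSS
summaries and the TSS-versus-expression regression we therefore use the
promoter-proximal window `[TSS−3 kb, TSS+1 kb)`, ending exactly where the
gene body begins, so the promoter and body measures never share a CpG. The
TTS-proximal summary window mirrors it.

## Methylation aggregation

Regional methylation is the **unweighted mean percent methylation over
covered CpGs** whose position falls in the region set. Read coverage is
retained for an optional minimum-coverage filter (default 1, i.e. off) but
is never used as a weight, and CpG dyads are not collapsed: each record is
an observation. A region with no covered CpG is missing (`NA`), never zero,
and missingness propagates through every downstream average.

Metagene profiles average fixed 100-bp windows per gene first, then average
the per-gene means within each expression bin (**gene-weighted**, not
site-weighted). This keeps CpG-dense genes from dominating a bin; the
pooling identity (combined mean = site-count-weighted mean of parts) is
exact and tested for the site-weighted primitive itself.

## Densities, promoters and the intron partition

* Tag density: tags whose **start position** falls in the region union,
  divided by the union's bp — single assignment, no double counting, exact
  linearity in tag multiplicity.
* CAGE activity: cluster tag count / cluster length (tags per bp).
* Cluster-to-intron assignment uses the **cluster midpoint**
  (`start + (width−1) %/% 2`); boundary-straddling clusters are not split.
  A strict-containment rule is available (`rule = "within"`).
* The intronic CAGE level divides summed intronic cluster tags by
  **intronic bp** by default, for comparability with the intron partition;
  `denominator = "locus"` reproduces the whole-locus reading. Loci without
  introns are missing, introns without clusters are 0.
* The intron partition intersects introns with the union of cluster spans;
  initiation and silent bp add up to intron bp exactly (a tested
  invariant).

## Binning and regression

Genes are ranked ascending and split into *k* equal-count bins (sizes
differ by ≤ 1, remainder to the lowest bins); ties are broken by the gene
identifier so that the assignment is permutation-invariant. Equal-count
(not equal-width) bins were chosen because expression is heavy-tailed and
equal-width value bins would leave most bins nearly empty.

The headline statistic is the Pearson correlation over the ≤ *k* (mean x,
mean y) bin points, with the two-sided *p* from the *t* transform on
*n*−2 df; the per-gene (raw) correlation is always reported alongside, since
binning inflates |r| by averaging out per-gene noise. A regression needs at
least 3 usable bins; constant input is an error ("undefined correlation"),
not a silent 0. With *k = n* the binned statistic reduces exactly to the
raw one. Binned-regression abscissas: expression bins for the body, TSS,
Pol2, DHSS and joint analyses; **activity bins** for the promoter
regressions (the quantity on the x axis); **silent-site methylation bins**
for the initiation-versus-silent comparison. The length-stratified check
repeats the body regression within the shortest and longest 20% of genes
with *k* = max(10, ⌊n/20⌋).

## The synthetic-data generator

The generator exists so that every stage can be validated end-to-end
against known truth. Its defaults are the package's study conditions, fixed
once:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `n_chroms` | 2000, 4 | genome size used throughout validation |
| `gene_length_mean`, spread | 6 kb, 0.45 sdlog | log-normal locus lengths (clamped 2.5–60 kb) |
| `gap_mean` | 4 kb | mean intergenic gap (min 600 bp) |
| `cpg_spacing` | 200 bp | mean spacing of covered CpGs (RRBS-like sparsity) |
| `expr_meanlog`, `expr_sdlog` | 2, 1.5 | log-normal expression (natural log) |
| `k_open`, `k_int`, `h_open`, `h_int` | 2, 30, 1, 1 | accessibility/interference half-points |
| `m_max` | 85% | peak expected body methylation |
| `tss_meth_max`, `tss_meth_decay` | 85%, 0.9 | logistic promoter demethylation vs log E |
| `intergenic_meth` | 10% | intergenic baseline |
| `cage_rate`, `cage_sat` | 1.2 / 10 kb, 5 | intronic initiation intensity, saturating in E |
| `cage_tag_scale`, `cage_meth_lambda` | 25, 0.04 | cluster tags ∝ exp(−λ·methylation) |
| `pol2_scale`, `pol2_exponent` | 0.02, 0.3 | Pol2 tags/bp = scale·E^0.3 |
| `dhss_scale`, `dhss_k` | 0.05, 7.5 | DHSS tags/bp = scale·E/(E+K) |
| `noise_sd` | 8% | per-CpG Gaussian noise |

The expected body methylation is the product of two Hill terms (opening ×
interference), peaking at `E* = sqrt(k_open·k_int) ≈ 7.75`, deliberately
placed near the median expression so the bell is visible across the whole
binned range. This product form is this package's quantitative stand-in
for a mechanism described qualitatively (nucleosome packaging blocking the
methyltransferase at low expression; polymerase traffic interfering with
its processivity at high expression); it is a model choice, with the two
required regimes and an analytic peak, not a measured curve.

Two link functions deserve a note. Chromatin-state tag rates are modelled
**compressively in expression** — a power law with exponent 0.3 for Pol2
and a Michaelis–Menten saturation for DHSS — because the empirical pattern
being emulated is a near-linear positive relation on the log2 expression
scale. A rate strictly linear in E would look strongly convex against
log2 E (for a log-normal E with sdlog σ, the correlation of E with log E is
only σ/√(e^σ²−1) ≈ 0.5 at σ = 1.5) and could not produce the strong
positive bin-mean correlations the pipeline is designed to detect.
Linearity in the scale parameters themselves is preserved (doubling
`pol2_scale` doubles expected density, a tested property).

Intronic CAGE clusters appear with intensity increasing in expression and
tag counts ∝ exp(−λ·M(E)): initiation is repressed where methylation is
high. Because M(E) falls at high expression, intragenic initiation rises
steeply among the most expressed genes — the joint inflection the `joint`
table and `compare_low_high()` expose. Clusters have odd widths and Pol2/
DHSS tags are single-bp 5' positions, so the midpoint and tag-start rules
are *exactly* invariant under coordinate mirroring, which the suite
exploits to test strand-flip invariance of the entire pipeline. Three CpGs
are planted symmetrically around each cluster midpoint (real CAGE clusters
are CpG-rich), so cluster methylation is measurable at RRBS-like sparsity.

What the generator does **not** emulate: CpG islands and RRBS fragment
bias, sequence context, bisulfite conversion error, multi-mapping tags,
cross-cell-line variation, antisense and nested genes beyond simple
overlapping isoform pairs, and distance-decaying correlation between
neighbouring CpGs (noise is i.i.d.). Passing the recovery tests therefore
shows the *pipeline arithmetic* is right under known truth, not that real
genomes behave this way.

## Numerical choices and degenerate inputs

* Pearson r is clamped to [−1, 1]; |r| = 1 maps to p = 0 directly.
* The direct-formula implementation is cross-checked against
  `stats::cor.test` to 1e−12 (r) / 1e−10 (p) in the suite.
* Zero-noise simulation recovers per-gene M(E) to 1e−9 (floating-point
  summation, otherwise exact).
* Empty bins, zero-CpG windows and loci without introns are `NA`; loci
  with no expressed member are dropped from binned analyses with a
  warning, never silently zero-filled.
* `run_all()` aborts with the failing stage's name; missing CAGE (or
  Pol2/DHSS) input skips only the dependent stages, with a warning.
* The low/high comparison splits at the median by default (the split
  quantile is a parameter) and refuses constant expression.
* All randomness flows from a single integer seed; stage functions derive
  fixed offsets (seed+1…+3) so each stage is independently reproducible.
  Identical seed and config give byte-identical summary JSON.

## Problem sizes

Validation runs use 2,000 genes on 4 chromosomes (≈ 22 Mb, ≈ 114k CpGs,
≈ 0.9M tags) for parameter- and sign-recovery, 200–400 genes for
invariance and determinism properties, and brute-force per-bp oracles on
≤ 100 kb toy genomes for the interval primitives. These sizes were chosen
so that binned statistics are stable (≥ 20 genes per bin at k = 100) while
the whole suite stays interactive.

## Interface note

The package is an analysis library: the documented functions compose with
the pipe and are the intended entry points (`simulate_dataset()`,
`merge_transcripts()`, `metagene_profile()`, `bin_regress()`,
`intronic_cage_level()`, `tag_density()`, `run_all()`), with
`scripts/acceptance.R` as the reproducible end-to-end driver.

## Known limitations

* BED12 is the only annotation format (no GTF/GFF in this version).
* The metagene body segment is a single overall mean per bin, not a
  per-gene length-scaled profile; scaled-body profiles are future work.
* No multiple-testing correction is applied across the reported
  regressions (they are few and pre-specified).
* The intronic-promoter methylation uses the cluster span only, without
  flanks; promoter-flank choices would need real data to calibrate.
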