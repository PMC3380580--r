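# genebody

Tools for genome-wide meta-analysis of **gene-body DNA methylation** against
gene expression and chromatin state, for epigenomics researchers working
with RRBS-style percent-methylation tracks, exon-array expression summaries,
CAGE tag clusters and ChIP-seq/DNase tag maps.

## The scientific problem

Promoter CpG methylation represses transcription, yet most methylation in
the human genome sits *inside* gene bodies and has been reported to
correlate positively with expression — the "DNA methylation paradox". This
package implements the analyses needed to interrogate that paradox at
genome scale:

* **Locus construction** — overlapping transcript models (BED12) are merged
  transitively into distinct gene loci spanning the 5'-most to the 3'-most
  exon, with strand-aware merging by default.
* **Regional methylation** — the methylation of any region set is the
  unweighted mean percent methylation of the covered CpGs inside it
  (coverage is recorded but never used as a weight). Metagene profiles
  average 100-bp windows spanning −3 kb…+5 kb around the TSS and
  −5 kb…+3 kb around the TTS, in transcription orientation. The *gene body*
  is the locus trimmed by 1 kb at each end (empty for loci ≤ 2 kb).
* **Promoter activity & chromatin** — CAGE cluster activity = tags /
  cluster length; intronic clusters (midpoint rule) mark intragenic
  promoters; Pol2 and DHSS tag density = tags mapping on a locus / locus
  length; introns partition exactly into initiation and silent sites.
* **Binned Pearson regression** — genes (or promoters) are ranked into *k*
  equal-count bins and the product-moment correlation

  $$r = \frac{\sum_i (\bar x_i - \bar x)(\bar y_i - \bar y)}
             {\sqrt{\sum_i (\bar x_i - \bar x)^2 \sum_i (\bar y_i - \bar y)^2}},
    \qquad t = r\sqrt{\tfrac{n-2}{1-r^2}}$$

  is computed over the bin means $(\bar x_i, \bar y_i)$, with a two-sided
  *p* from the *t* transform (the per-gene correlation is reported
  alongside).

Because the full analysis needs genome-scale inputs, the package ships a
**synthetic-data generator** whose expected gene-body methylation follows an
accessibility–interference model: closed chromatin blocks the
methyltransferase at low expression, and dense transiting polymerase
interferes with its processivity at high expression,

$$M(E) = M_{\max}\;
  \frac{E^{h_1}}{E^{h_1}+K_{\mathrm{open}}^{h_1}}\;
  \frac{K_{\mathrm{int}}^{h_2}}{K_{\mathrm{int}}^{h_2}+E^{h_2}},$$

which peaks at $E^\* = \sqrt{K_{\mathrm{open}} K_{\mathrm{int}}}$ for
$h_1 = h_2$ and produces the bell-shaped body-methylation curve together
with monotone promoter demethylation, rising Pol2/DHSS density and
methylation-repressed intragenic initiation.

## Worked example

```r
library(genebody)

sim <- simulate_dataset(sim_config(n_genes = 500, seed = 1))
run <- run_all(sim, bins = 50)
run
#> Gene-body methylation meta-analysis: 500 loci
#>
#> # A tibble: 9 × 7
#>   analysis                              r        p n_bins peak_bin     k   r_raw
#>   <chr>                             <dbl>    <dbl>  <int>    <int> <dbl>   <dbl>
#> 1 body_meth_vs_expr               -0.0415 7.75e- 1     50       25    50 -0.0414
#> 2 tss_meth_vs_expr                -0.980  1.85e-35     50        1    50 -0.905
#> 3 body_meth_vs_expr_short         -0.263  4.63e- 1     10        5    10 -0.247
#> 4 body_meth_vs_expr_long           0.0430 9.06e- 1     10        5    10  0.0410
#> 5 intronic_promoter_meth_vs_acti… -0.882  5.92e-15     43        6    43 -0.821
#> 6 canonical_promoter_meth_vs_act… -0.634  7.80e- 7     50        3    50 -0.548
#> 7 initiation_vs_silent_meth        0.952  1.56e-18     35       31    35  0.925
#> 8 pol2_density_vs_expr             0.958  9.36e-28     50       50    50  0.948
#> 9 dhss_density_vs_expr             0.982  1.67e-36     50       50    50  0.972
#>
#> Genic 40.1% vs intergenic 25.9% methylation
```

How to read this: the gene-body methylation regression has |r| ≈ 0 across
50 expression bins *because the relationship is bell-shaped, not linear* —
its peak bin (25 of 50) sits at mid-range expression, right where the model
places $E^\* $ ($\log_2 E^\* \approx 2.95$, the median of the expression
distribution). Promoter (TSS) methylation falls monotonically with
expression (r = −0.98), Pol2 and open-chromatin density rise with it
(r = +0.96, +0.98), intragenic promoter methylation represses initiation
(r = −0.88), and initiation/silent intronic sites are methylated alike
(r = +0.95) — gene bodies, not just their promoters, carry the methylation.
Genic methylation (40.1%) exceeds intergenic (25.9%).

```r
run$low_high
#> # A tibble: 2 × 7
#>   group     n mean_expr mean_meth se_meth mean_intronic_cage se_intronic_cage
#> 1 low     250      1.22      40.8   0.837           0.000131        0.0000329
#> 2 high    250      4.82      39.3   0.842           0.000629        0.000109
```

Highly expressed genes initiate ~5× more intragenic transcription than
lowly expressed genes while carrying slightly *less* body methylation — the
joint pattern that motivates the accessibility model.

Individual stages compose with the pipe, e.g.

```r
loci <- merge_transcripts(sim$transcripts)
loci |>
  locus_expression(sim$expression) |>
  dplyr::left_join(locus_tag_density(sim$pol2, loci), by = "locus_id") |>
  bin_regress(log2_expr, density, k = 100) |>
  glance()
```

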