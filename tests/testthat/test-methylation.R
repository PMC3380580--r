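# Per-CpG aggregation, pooling, metagene window placement and the
# genic/intergenic summary.

test_that("region methylation is the unweighted per-CpG mean", {
  cpgs <- cpg_tbl("chr1", c(150, 250, 800), c(50, 100, 30),
                  coverage = c(5L, 50L, 10L))
  reg <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  got <- region_methylation(cpgs, reg)
  expect_equal(got$mean_percent, 75) # coverage is NOT a weight
  expect_equal(got$n_sites, 2L)

  none <- region_methylation(cpgs, tibble::tibble(chrom = "chr1",
                                                  start = 400L, end = 500L))
  expect_true(is.na(none$mean_percent))
  expect_equal(none$n_sites, 0L)
})

test_that("disjoint region sets pool by site count", {
  # region A: 3 CpGs mean 20; region B: 1 CpG at 60 -> pooled (3*20+60)/4
  cpgs <- cpg_tbl("chr1", c(10, 20, 30, 100), c(10, 20, 30, 60))
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L)
  b <- tibble::tibble(chrom = "chr1", start = 90L, end = 110L)
  both <- region_methylation(cpgs, dplyr::bind_rows(a, b))
  expect_equal(both$mean_percent, 30)
  # exact pooling property
  ma <- region_methylation(cpgs, a)
  mb <- region_methylation(cpgs, b)
  expect_equal(both$mean_percent,
               (ma$mean_percent * ma$n_sites + mb$mean_percent * mb$n_sites) /
                 (ma$n_sites + mb$n_sites))
  # a CpG covered by two overlapping regions of one set counts once
  dup <- region_methylation(cpgs, tibble::tibble(
    chrom = "chr1", start = c(0L, 5L), end = c(50L, 40L)))
  expect_equal(dup$n_sites, 3L)
})

test_that("grouped aggregation and the coverage filter work", {
  cpgs <- cpg_tbl("chr1", c(10, 20, 200), c(0, 100, 40),
                  coverage = c(2L, 8L, 8L))
  regs <- tibble::tibble(chrom = "chr1", start = c(0L, 150L),
                         end = c(100L, 300L), locus_id = c("a", "b"))
  got <- region_methylation(cpgs, regs, by = "locus_id")
  expect_equal(got$mean_percent[got$locus_id == "a"], 50)
  expect_equal(got$mean_percent[got$locus_id == "b"], 40)
  filt <- region_methylation(cpgs, regs, by = "locus_id", min_coverage = 5)
  expect_equal(filt$mean_percent[filt$locus_id == "a"], 100)
  # agreement with the brute-force per-bp scan on random fixtures
  set.seed(7)
  for (rep in 1:20) {
    cp <- cpg_tbl("chr1", sample(0:999, 40), runif(40, 0, 100))
    rr <- tibble::tibble(chrom = "chr1", start = sample(0:900, 5))
    rr$end <- rr$start + sample(10:150, 5, replace = TRUE)
    want <- bf_region_meth(cp, rr)
    got <- region_methylation(cp, rr)
    expect_equal(got$mean_percent, want$mean)
    expect_equal(got$n_sites, want$n)
  }
})

test_that("metagene windows sit at the anchors in transcription orientation", {
  loci <- merge_transcripts(make_transcripts(
    tx_row("chr1", 10000, 20000, "plus", "+"),
    tx_row("chr2", 10000, 20000, "minus", "-")
  ))
  reg <- derive_regions(loci)
  # one CpG 50 bp downstream of each TSS (orientation-aware)
  cpgs <- dplyr::bind_rows(
    cpg_tbl("chr1", 10050, 80),   # + strand: offset 0 window [tss, tss+100)
    cpg_tbl("chr2", 19949, 60)    # - strand: offset 0 window [tss-99, tss+1)
  )
  bins <- tibble::tibble(locus_id = loci$locus_id, bin = 1L)
  prof <- metagene_profile(cpgs, reg, bins)$profile
  w0 <- prof[prof$anchor == "TSS" & prof$offset == 0, ]
  expect_equal(w0$mean_percent, 70) # gene-weighted mean of 80 and 60
  expect_equal(w0$n_genes, 2L)
  # no other TSS window sees a CpG
  expect_equal(sum(prof$n_genes[prof$anchor == "TSS"]), 2L)
})

test_that("metagene profile is invariant under genome mirroring", {
  sim <- small_sim(n_genes = 60, seed = 9)
  loci <- merge_transcripts(sim$transcripts)
  reg <- derive_regions(loci, sim$chrom_sizes)
  bins <- tibble::tibble(locus_id = loci$locus_id,
                         bin = rep_len(1:2, nrow(loci)))
  p1 <- metagene_profile(sim$methylome, reg, bins)$profile
  mir <- mirror_dataset(sim)
  loci_m <- merge_transcripts(mir$transcripts)
  reg_m <- derive_regions(loci_m, mir$chrom_sizes)
  # same genes in mirrored coordinate order; map bins via span identity
  key <- paste(loci$chrom, loci$start)
  key_m <- paste(loci_m$chrom,
                 sim$chrom_sizes$size[match(loci_m$chrom, sim$chrom_sizes$chrom)] -
                   loci_m$end)
  bins_m <- tibble::tibble(locus_id = loci_m$locus_id,
                           bin = bins$bin[match(key_m, key)])
  p2 <- metagene_profile(mir$methylome, reg_m, bins_m)$profile
  expect_equal(p2$mean_percent, p1$mean_percent, tolerance = 1e-9)
  expect_equal(p2$n_genes, p1$n_genes)
})

test_that("genic/intergenic summary conserves sites and computes SE", {
  loci <- merge_transcripts(make_transcripts(tx_row("chr1", 100, 500, "A")))
  cpgs <- cpg_tbl("chr1", c(150, 250, 350, 700, 800, 900),
                  c(10, 20, 30, 20, 20, 20))
  gi <- genic_vs_intergenic(cpgs, loci)
  genic <- gi[gi$class == "genic", ]
  expect_equal(genic$mean_percent, 20)
  expect_equal(genic$se, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(sum(gi$n_sites), nrow(cpgs))

  all_out <- genic_vs_intergenic(cpg_tbl("chr1", 700, 50), loci)
  expect_true(is.na(all_out$mean_percent[all_out$class == "genic"]))
  expect_error(
    genic_vs_intergenic(cpgs, loci,
                        tibble::tibble(chrom = "chr1", size = 600)),
    "bounds")
})
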