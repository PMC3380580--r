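# The synthetic-data generator: determinism, model limits, moment checks,
# file round-trips and the mirroring transform.

test_that("the accessibility-interference model has the right shape", {
  cfg <- sim_config()
  es <- e_star(cfg)
  expect_equal(es, sqrt(cfg$k_open * cfg$k_int))
  # maximal at E*, vanishing at both extremes
  expect_gt(body_methylation_mean(es, cfg),
            body_methylation_mean(es / 10, cfg))
  expect_gt(body_methylation_mean(es, cfg),
            body_methylation_mean(es * 10, cfg))
  expect_lt(body_methylation_mean(1e-6, cfg), 1e-4)
  expect_lt(body_methylation_mean(1e9, cfg), 1e-2)
  # numeric maximisation agrees with the closed form, also for unequal Hill
  # coefficients
  num <- stats::optimize(function(z) body_methylation_mean(exp(z), cfg),
                         interval = log(c(1e-4, 1e6)), maximum = TRUE)
  expect_equal(exp(num$maximum), es, tolerance = 1e-4)
  cfg2 <- sim_config(h_open = 2, h_int = 1)
  es2 <- e_star(cfg2)
  eps <- 1e-3
  expect_gte(body_methylation_mean(es2, cfg2),
             body_methylation_mean(es2 * (1 + eps), cfg2))
  expect_gte(body_methylation_mean(es2, cfg2),
             body_methylation_mean(es2 * (1 - eps), cfg2))
  # promoter methylation decays monotonically with expression
  E <- exp(seq(-2, 6, 0.5))
  expect_true(all(diff(tss_methylation_mean(E, cfg)) < 0))
})

test_that("a YAML config file round-trips into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 77", "seed: 9", "noise_sd: 4", "k_int: 20"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 77)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$k_int, 20)
  expect_equal(cfg$cpg_spacing, sim_config()$cpg_spacing) # defaults kept
  writeLines("bogus_key: 1", path)
  expect_error(read_sim_config(path), "unknown")
})

test_that("simulation is deterministic given the seed", {
  s1 <- small_sim(n_genes = 50, seed = 21)
  s2 <- small_sim(n_genes = 50, seed = 21)
  for (el in c("transcripts", "chrom_sizes", "expression", "methylome",
               "cage", "pol2", "dhss", "truth")) {
    expect_identical(s1[[el]], s2[[el]])
  }
  s3 <- small_sim(n_genes = 50, seed = 22)
  expect_false(identical(s1$methylome, s3$methylome))
  expect_false(identical(s1$transcripts$start, s3$transcripts$start))
})

test_that("annotation is non-pathological and exercises merging", {
  sim <- small_sim(n_genes = 80, seed = 13)
  tx <- sim$transcripts
  expect_gte(nrow(tx), 80)
  expect_gt(nrow(tx), 80 * 0.99) # some overlapping second transcripts
  loci <- merge_transcripts(tx)
  expect_equal(nrow(loci), 80)  # overlapping pairs merge back to genes
  expect_true(any(loci$n_members > 1))
  expect_true(all(lengths(loci$exon_starts) >= 1))
  # loci stay within chromosome bounds
  sz <- sim$chrom_sizes$size[match(loci$chrom, sim$chrom_sizes$chrom)]
  expect_true(all(loci$end <= sz))
})

test_that("expression is log-normal with the configured moments", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_dataset(cfg)
  lE <- log(sim$truth$E)
  n <- length(lE)
  # sample mean of log E within 3 SE of the theoretical meanlog
  expect_lt(abs(mean(lE) - cfg$expr_meanlog), 3 * cfg$expr_sdlog / sqrt(n))
  expect_lt(abs(sd(lE) - cfg$expr_sdlog), 0.1)
  # degenerate limit: zero spread collapses to a point
  flat <- simulate_dataset(sim_config(n_genes = 30, expr_sdlog = 0, seed = 3))
  expect_equal(diff(range(flat$truth$E)), 0)
})

test_that("a zero-noise methylome recovers M(E) exactly per gene", {
  sim <- small_sim(n_genes = 120, seed = 31, noise_sd = 0)
  loci <- merge_transcripts(sim$transcripts)
  reg <- derive_regions(loci, sim$chrom_sizes)
  body <- reg[!is.na(reg$body_start), ]
  got <- region_methylation(
    sim$methylome,
    tibble::tibble(chrom = body$chrom, start = body$body_start,
                   end = body$body_end, locus_id = body$locus_id),
    by = "locus_id")
  # map loci back to genes via their span
  gene_of <- sim$truth$gene_id[match(paste(body$chrom, body$body_start),
                                     paste(sim$truth$chrom,
                                           sim$truth$start + 1000L))]
  want <- sim$truth$m_body[match(gene_of, sim$truth$gene_id)]
  ok <- !is.na(got$mean_percent)
  expect_gt(mean(ok), 0.95)
  expect_equal(got$mean_percent[ok], want[ok], tolerance = 1e-9)
})

test_that("intergenic methylation sits below the genic mean by construction", {
  sim <- small_sim(n_genes = 150, seed = 8)
  gi <- genic_vs_intergenic(sim$methylome, merge_transcripts(sim$transcripts),
                            sim$chrom_sizes)
  expect_gt(gi$mean_percent[gi$class == "genic"],
            gi$mean_percent[gi$class == "intergenic"])
})

test_that("cage_rate = 0 silences intragenic initiation", {
  sim <- small_sim(n_genes = 60, seed = 14, cage_rate = 0)
  expect_true(all(sim$cage$type == "canonical"))
  loci <- merge_transcripts(sim$transcripts)
  part <- partition_introns(locus_introns(loci), cage_activity(sim$cage))
  summ <- partition_summary(part)
  expect_true(all(summ$fraction_initiation == 0))
})

test_that("doubling the Pol2 rate doubles expected density", {
  s1 <- small_sim(n_genes = 400, seed = 17)
  s2 <- small_sim(n_genes = 400, seed = 17, pol2_scale = 0.04)
  d1 <- nrow(s1$pol2)
  d2 <- nrow(s2$pol2)
  # Poisson totals: ratio within 3 SE of 2
  se <- 2 * sqrt(1 / d1 + 1 / d2)
  expect_lt(abs(d2 / d1 - 2), 3 * 2 * se)
})

test_that("emitted files round-trip losslessly through the readers", {
  sim <- small_sim(n_genes = 40, seed = 25)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  # every file carries the seed header
  for (f in list.files(dir, full.names = TRUE)) {
    expect_match(readLines(f, n = 1), "seed=25", fixed = TRUE)
  }
  back <- read_sim_dataset(dir)
  expect_equal(back$transcripts$exon_starts, sim$transcripts$exon_starts)
  expect_equal(back$transcripts$name, sim$transcripts$name)
  expect_equal(back$methylome$percent, sim$methylome$percent)
  expect_equal(back$methylome$start, sim$methylome$start)
  expect_equal(back$expression$log2_expr, sim$expression$log2_expr)
  expect_equal(back$cage$score, sim$cage$score)
  expect_equal(back$pol2$start, sim$pol2$start)
  expect_equal(back$chrom_sizes, sim$chrom_sizes)
  expect_equal(back$truth$E, sim$truth$E)
})

test_that("mirroring is an involution and preserves bp content", {
  sim <- small_sim(n_genes = 50, seed = 29)
  mir <- mirror_dataset(sim)
  twice <- mirror_dataset(mir)
  expect_equal(dplyr::arrange(twice$methylome, chrom, start),
               dplyr::arrange(sim$methylome, chrom, start))
  expect_equal(sort(twice$transcripts$start), sort(sim$transcripts$start))
  # widths preserved
  expect_equal(sort(mir$cage$end - mir$cage$start),
               sort(sim$cage$end - sim$cage$start))
})
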