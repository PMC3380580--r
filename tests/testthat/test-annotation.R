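# Locus construction: BED12 round-trip, transcript merging, region
# derivation and the intergenic complement.

test_that("BED12 round-trip preserves transcript models", {
  tx <- make_transcripts(
    tx_row("chr1", 100, 900, "tx1", "+",
           exons = list(c(100, 200), c(700, 900))),
    tx_row("chr1", 950, 1200, "tx2", "-")
  )
  path <- withr::local_tempfile(fileext = ".bed12")
  write_transcripts(tx, path, header = "fixture")
  back <- read_transcripts(path)
  expect_equal(back$chrom, tx$chrom)
  expect_equal(back$start, tx$start)
  expect_equal(back$end, tx$end)
  expect_equal(back$name, tx$name)
  expect_equal(back$strand, tx$strand)
  expect_equal(back$exon_starts, tx$exon_starts)
  expect_equal(back$exon_ends, tx$exon_ends)
  # the two-block transcript implies intron [200, 700)
  introns <- locus_introns(merge_transcripts(back))
  i1 <- introns[introns$start == 200, ]
  expect_equal(i1$end, 700L)
})

test_that("empty and single-block inputs parse", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("# nothing here", path)
  expect_equal(nrow(read_transcripts(path)), 0)
  writeLines("chr1\t0\t500\ttx1\t0\t+\t0\t500\t0\t1\t500,\t0,", path)
  one <- read_transcripts(path)
  expect_equal(one$exon_starts[[1]], 0L)
  expect_equal(one$exon_ends[[1]], 500L)
  expect_equal(nrow(locus_introns(merge_transcripts(one))), 0)
})

test_that("inconsistent exon blocks are rejected with the offending line", {
  bad <- tx_row("chr1", 100, 900, "oops", "+",
                exons = list(c(100, 200), c(700, 950)))
  expect_error(validate_transcripts <- genebody::merge_transcripts(bad),
               "oops")
})

test_that("overlap merging matches the brute-force union-find oracle", {
  # transitive closure: A overlaps B, B overlaps C, A and C do not
  tx <- make_transcripts(
    tx_row("chr1", 100, 400, "A"),
    tx_row("chr1", 350, 700, "B"),
    tx_row("chr1", 650, 900, "C")
  )
  loci <- merge_transcripts(tx)
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(100L, 900L))
  expect_setequal(loci$members[[1]], c("A", "B", "C"))

  # disjoint and abutting spans stay separate
  tx2 <- make_transcripts(tx_row("chr1", 100, 500, "A"),
                          tx_row("chr1", 500, 900, "B"),
                          tx_row("chr1", 950, 990, "C"))
  expect_equal(nrow(merge_transcripts(tx2)), 3)

  # opposite strands merge only when strand_aware = FALSE
  tx3 <- make_transcripts(tx_row("chr1", 100, 500, "A", "+"),
                          tx_row("chr1", 400, 800, "B", "-"))
  expect_equal(nrow(merge_transcripts(tx3, strand_aware = TRUE)), 2)
  blind <- merge_transcripts(tx3, strand_aware = FALSE)
  expect_equal(nrow(blind), 1)
  expect_equal(blind$strand, "*")

  # randomized check against the oracle
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    s <- sample(0:5000, n, replace = TRUE)
    tx_r <- make_transcripts(!!!purrr::pmap(
      list(s, s + sample(50:2000, n, replace = TRUE),
           sprintf("t%02d", seq_len(n)),
           sample(c("+", "-"), n, replace = TRUE)),
      function(a, b, nm, st) tx_row("chr1", a, b, nm, st)
    ))
    got <- merge_transcripts(tx_r)
    want <- bf_merge(tx_r)
    expect_equal(nrow(got), length(want))
    expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"),
                 ignore_attr = TRUE)
    expect_equal(purrr::map(got$members, sort),
                 purrr::map(want, "members"), ignore_attr = TRUE)
    # member conservation and idempotence
    expect_equal(sum(got$n_members), n)
    again <- merge_transcripts(tibble::tibble(
      chrom = got$chrom, start = got$start, end = got$end,
      name = got$locus_id, score = 0, strand = got$strand,
      exon_starts = got$exon_starts, exon_ends = got$exon_ends
    ))
    expect_equal(again[, c("chrom", "start", "end", "strand")],
                 got[, c("chrom", "start", "end", "strand")])
  }
})

test_that("regions are strand-symmetric and bodies need > 2 kb", {
  loci <- merge_transcripts(make_transcripts(
    tx_row("chr1", 10000, 20000, "plus", "+"),
    tx_row("chr2", 10000, 20000, "minus", "-"),
    tx_row("chr3", 10000, 11500, "short", "+")
  ))
  reg <- derive_regions(loci)
  plus <- reg[reg$strand == "+" & reg$chrom == "chr1", ]
  minus <- reg[reg$strand == "-", ]
  short <- reg[reg$chrom == "chr3", ]
  expect_equal(c(plus$tss, plus$tts), c(10000L, 19999L))
  expect_equal(c(plus$body_start, plus$body_end), c(11000L, 19000L))
  expect_equal(c(minus$tss, minus$tts), c(19999L, 10000L))
  expect_equal(c(minus$body_start, minus$body_end), c(11000L, 19000L))
  # flanks mirror: plus TSS flank [7000, 15000), minus [5000, 23000) TSS side
  expect_equal(c(plus$tss_flank_start, plus$tss_flank_end), c(7000L, 15000L))
  expect_equal(c(minus$tss_flank_start, minus$tss_flank_end),
               c(15000L, 23000L))
  expect_true(is.na(short$body_start))
})

test_that("flank windows are clipped at chromosome bounds", {
  loci <- merge_transcripts(make_transcripts(tx_row("chr1", 500, 4000, "edge")))
  sizes <- tibble::tibble(chrom = "chr1", size = 6000)
  reg <- derive_regions(loci, chrom_sizes = sizes)
  expect_equal(reg$tss_flank_start, 0L)
  expect_equal(reg$tts_flank_end, 6000L)
})

test_that("intergenic complement matches a per-bp membership scan", {
  loci <- merge_transcripts(make_transcripts(tx_row("chr1", 100, 900, "A")))
  sizes <- tibble::tibble(chrom = "chr1", size = 1000)
  comp <- intergenic_complement(loci, sizes)
  expect_equal(comp$start, c(0L, 900L))
  expect_equal(comp$end, c(100L, 1000L))

  # overlapping loci on both strands
  loci2 <- merge_transcripts(make_transcripts(
    tx_row("chr1", 100, 500, "A", "+"), tx_row("chr1", 400, 800, "B", "-")))
  comp2 <- intergenic_complement(loci2, sizes)
  expect_equal(comp2$start, c(0L, 800L))
  expect_equal(comp2$end, c(100L, 1000L))

  # loci tiling the chromosome leave nothing
  loci3 <- merge_transcripts(make_transcripts(tx_row("chr1", 0, 1000, "A")))
  expect_equal(nrow(intergenic_complement(loci3, sizes)), 0)

  # randomized per-bp oracle
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    s <- sample(0:900, n, replace = TRUE)
    txr <- make_transcripts(!!!purrr::map(seq_len(n), function(i) {
      tx_row("chr1", s[i], min(1000, s[i] + sample(20:300, 1)),
             paste0("t", i))
    }))
    lc <- merge_transcripts(txr)
    cmp <- intergenic_complement(lc, sizes)
    member <- rep(FALSE, 1000)
    for (i in seq_len(nrow(lc))) {
      member[seq.int(lc$start[i] + 1, lc$end[i])] <- TRUE
    }
    cmp_bp <- unlist(Map(seq.int, cmp$start + 1, cmp$end))
    expect_setequal(cmp_bp, which(!member))
    # complement and loci tile the chromosome exactly
    expect_equal(sum(cmp$end - cmp$start) + sum(member), 1000)
  }

  expect_error(intergenic_complement(
    merge_transcripts(make_transcripts(tx_row("chr1", 100, 2000, "A"))),
    sizes), "beyond")
})

test_that("mirroring coordinates and strands mirrors the loci", {
  tx <- make_transcripts(
    tx_row("chr1", 100, 900, "tx1", "+",
           exons = list(c(100, 300), c(600, 900))),
    tx_row("chr1", 700, 1200, "tx2", "+")
  )
  L <- 2000
  data <- list(transcripts = tx,
               chrom_sizes = tibble::tibble(chrom = "chr1", size = L))
  mir <- mirror_dataset(data)
  loci <- merge_transcripts(tx)
  loci_m <- merge_transcripts(mir$transcripts)
  expect_equal(loci_m$start, L - rev(loci$end))
  expect_equal(loci_m$end, L - rev(loci$start))
  expect_equal(loci_m$strand, rev(ifelse(loci$strand == "+", "-", "+")))
  # TSS maps to TSS
  reg <- derive_regions(loci)
  reg_m <- derive_regions(loci_m)
  expect_equal(reg_m$tss, L - 1 - rev(reg$tss))
})
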