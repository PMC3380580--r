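# Fixture builders and independent brute-force oracles used across the
# suite. All fixtures are constructed in code; nothing is read from disk
# except temp files written by the tests themselves.

tx_row <- function(chrom, start, end, name, strand = "+", exons = NULL) {
  if (is.null(exons)) exons <- list(c(start, end))
  es <- vapply(exons, `[`, numeric(1), 1)
  ee <- vapply(exons, `[`, numeric(1), 2)
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, score = 0, strand = strand,
    exon_starts = list(as.integer(es)), exon_ends = list(as.integer(ee))
  )
}

make_transcripts <- function(...) dplyr::bind_rows(...)

cpg_tbl <- function(chrom, pos, percent, coverage = 10L) {
  tibble::tibble(chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos) + 1L, percent = percent,
                 coverage = as.integer(coverage))
}

# --- brute-force oracles -------------------------------------------------

# Union-find merge over pairwise span overlaps (>= 1 shared bp).
bf_merge <- function(tx, strand_aware = TRUE) {
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      same <- tx$chrom[i] == tx$chrom[j] &&
        (!strand_aware || tx$strand[i] == tx$strand[j])
      overlap <- max(tx$start[i], tx$start[j]) < min(tx$end[i], tx$end[j])
      if (same && overlap) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  out <- lapply(comps, function(idx) {
    list(chrom = tx$chrom[idx[1]],
         start = min(tx$start[idx]), end = max(tx$end[idx]),
         members = sort(tx$name[idx]))
  })
  out[order(vapply(out, function(x) paste(x$chrom, sprintf("%012d", x$start)),
                   character(1)))]
}

# Per-bp membership scan: mean methylation of CpGs inside any region.
bf_region_meth <- function(cpgs, regions) {
  inside <- vapply(seq_len(nrow(cpgs)), function(i) {
    any(regions$chrom == cpgs$chrom[i] &
          regions$start <= cpgs$start[i] & cpgs$start[i] < regions$end)
  }, logical(1))
  if (!any(inside)) return(list(mean = NA_real_, n = 0L))
  list(mean = mean(cpgs$percent[inside]), n = sum(inside))
}

# Naive tag density: unique bp of the region union and tag starts inside it.
bf_tag_density <- function(tags, regions) {
  bp <- 0
  hit <- rep(FALSE, nrow(tags))
  for (ch in unique(regions$chrom)) {
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    cov_bp <- unique(unlist(Map(seq.int, rr$start, rr$end - 1)))
    bp <- bp + length(cov_bp)
    ti <- which(tags$chrom == ch)
    hit[ti] <- tags$start[ti] %in% cov_bp
  }
  sum(hit) / bp
}

# Per-bp partition of introns into initiation/silent bp.
bf_partition_bp <- function(introns, clusters) {
  res <- lapply(split(seq_len(nrow(introns)), introns$locus_id), function(idx) {
    ini_bp <- 0L
    sil_bp <- 0L
    for (i in idx) {
      for (p in seq.int(introns$start[i], introns$end[i] - 1L)) {
        in_cl <- any(clusters$chrom == introns$chrom[i] &
                       clusters$start <= p & p < clusters$end)
        if (in_cl) ini_bp <- ini_bp + 1L else sil_bp <- sil_bp + 1L
      }
    }
    c(initiation = ini_bp, silent = sil_bp)
  })
  res
}

bf_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# --- shared expensive fixtures (built lazily, once per session) ----------

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_dataset(sim_config(seed = 42))
  }
  .fixture_cache$sim
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- suppressWarnings(run_all(default_sim()))
  }
  .fixture_cache$run
}

small_sim <- function(n_genes = 200, seed = 5, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
}
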