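# Synthetic-data generator. Produces a toy genome (transcripts, expression,
# methylome, CAGE clusters, Pol2 and DHSS tags) whose statistical structure
# instantiates an accessibility-interference model of gene-body methylation:
# chromatin opening makes CpGs available to the methyltransferase as
# expression rises, while at high expression dense transiting polymerase
# interferes with its processivity. The expected gene-body methylation is a
# product of two Hill terms,
#   M(E) = M_max * E^h1 / (E^h1 + K_open^h1) * K_int^h2 / (K_int^h2 + E^h2),
# maximal (for h1 = h2) at E* = sqrt(K_open * K_int).

#' Simulation configuration
#'
#' All tunable parameters of the synthetic-data generator with their
#' defaults. Lengths are in bp, expression on the natural (linear) scale,
#' methylation in percent.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (genes split evenly).
#' @param gene_length_mean,gene_length_spread Log-normal gene length
#'   (median bp and sdlog).
#' @param gap_mean Mean intergenic gap (bp, minimum 600).
#' @param exons_per_gene Mean number of exons per gene (>= 1).
#' @param cpg_spacing Mean bp between consecutive covered CpGs.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters (natural
#'   log scale).
#' @param k_open,h_open Half-saturation expression and Hill coefficient of
#'   the chromatin-opening term.
#' @param k_int,h_int Half-inhibition expression and Hill coefficient of the
#'   polymerase-interference term.
#' @param m_max Maximal mean gene-body methylation (percent).
#' @param tss_meth_max Promoter methylation at very low expression (percent).
#' @param tss_meth_decay Slope of the logistic promoter demethylation versus
#'   log expression.
#' @param intergenic_meth Mean intergenic baseline methylation (percent).
#' @param cage_rate Intronic initiation intensity (expected clusters per
#'   10 kb of intron at saturating expression).
#' @param cage_sat Half-saturation expression of the intronic cluster count.
#' @param cage_tag_scale Expected tags of an unmethylated intronic cluster.
#' @param cage_meth_lambda Exponential decay of cluster activity per percent
#'   methylation (the repression of intragenic initiation by methylation).
#' @param cluster_width CAGE cluster footprint (bp; forced odd so the
#'   midpoint is exact).
#' @param tss_cluster_scale Expected canonical-promoter tags per expression
#'   unit.
#' @param pol2_scale,pol2_exponent Pol2 tag rate: expected tags per bp =
#'   `pol2_scale * E^pol2_exponent`.
#' @param dhss_scale,dhss_k DHSS tag rate: expected tags per bp =
#'   `dhss_scale * E / (E + dhss_k)` (saturating open-chromatin link).
#' @param noise_sd Per-CpG Gaussian noise (percent).
#' @param overlap_frac Fraction of genes emitting a second, overlapping
#'   transcript (exercises locus merging).
#' @param seed RNG seed; recorded in every output file header.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_genes = 2000, n_chroms = 4,
                       gene_length_mean = 6000, gene_length_spread = 0.45,
                       gap_mean = 4000, exons_per_gene = 4,
                       cpg_spacing = 200,
                       expr_meanlog = 2, expr_sdlog = 1.5,
                       k_open = 2, h_open = 1, k_int = 30, h_int = 1,
                       m_max = 85,
                       tss_meth_max = 85, tss_meth_decay = 0.9,
                       intergenic_meth = 10,
                       cage_rate = 1.2, cage_sat = 5,
                       cage_tag_scale = 25, cage_meth_lambda = 0.04,
                       cluster_width = 51, tss_cluster_scale = 2,
                       pol2_scale = 0.02, pol2_exponent = 0.3,
                       dhss_scale = 0.05, dhss_k = 7.5,
                       noise_sd = 8, overlap_frac = 0.15, seed = 1) {
  cfg <- as.list(environment())
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, function(v) is.numeric(v) && v >= 0, logical(1)))) {
    abort("all sim_config parameters must be non-negative numbers")
  }
  if (n_genes < 1 || n_chroms < 1) abort("need n_genes >= 1, n_chroms >= 1")
  cfg$cluster_width <- as.integer(cluster_width) + (as.integer(cluster_width) %% 2L == 0L)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' The file holds [sim_config()] keys verbatim; omitted keys take their
#' defaults and unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed", x$seed, "):",
      x$n_genes, "genes on", x$n_chroms, "chromosomes; E* =",
      signif(e_star(x), 4), "\n")
  invisible(x)
}

#' Expected gene-body methylation under the accessibility-interference model
#'
#' @param E Expression on the linear scale.
#' @param config A [sim_config()].
#' @return Mean percent methylation.
#' @export
body_methylation_mean <- function(E, config) {
  open <- E^config$h_open / (E^config$h_open + config$k_open^config$h_open)
  interf <- config$k_int^config$h_int / (config$k_int^config$h_int + E^config$h_int)
  config$m_max * open * interf
}

#' Expected promoter (TSS-proximal) methylation
#'
#' Logistic decay in log expression: highly expressed genes have demethylated
#' promoters.
#'
#' @inheritParams body_methylation_mean
#' @return Mean percent methylation.
#' @export
tss_methylation_mean <- function(E, config) {
  config$tss_meth_max /
    (1 + exp(config$tss_meth_decay * (log(E) - config$expr_meanlog)))
}

#' Expression at which gene-body methylation peaks
#'
#' Closed form `sqrt(k_open * k_int)` when the two Hill coefficients are
#' equal; otherwise found numerically.
#'
#' @param config A [sim_config()].
#' @return The peak expression E* (linear scale).
#' @export
e_star <- function(config) {
  if (config$h_open == config$h_int) {
    return(sqrt(config$k_open * config$k_int))
  }
  exp(optimize(function(z) body_methylation_mean(exp(z), config),
               interval = log(c(1e-6, 1e6)) + config$expr_meanlog,
               maximum = TRUE)$maximum)
}

# Relative exon layout for a gene of `len` bp with `n_ex` exons: alternating
# exon/intron segments, each >= 60 bp.
make_exon_layout <- function(len, n_ex) {
  n_ex <- max(1L, min(n_ex, len %/% 400L))
  if (n_ex == 1L) return(list(starts = 0L, ends = as.integer(len)))
  nseg <- 2L * n_ex - 1L
  w <- rexp(nseg) + 0.3
  seg <- pmax(60L, as.integer(floor(len * w / sum(w))))
  seg[which.max(seg)] <- seg[which.max(seg)] + (len - sum(seg))
  if (any(seg < 60L)) return(list(starts = 0L, ends = as.integer(len)))
  b <- cumsum(c(0L, seg))
  odd <- seq(1L, nseg, by = 2L)
  list(starts = b[odd], ends = b[odd + 1L])
}

#' Simulate gene annotation
#'
#' Places non-overlapping genes with intergenic gaps along `n_chroms`
#' chromosomes; a fraction of genes emit a second overlapping transcript so
#' that locus merging is exercised. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `transcripts` (BED12-shaped tibble as from
#'   [read_transcripts()]), `chrom_sizes`, and `genes` (per-gene truth
#'   scaffold with exon-union list-columns).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chroms)
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- as.integer(clip01(
    round(rlnorm(n, log(config$gene_length_mean), config$gene_length_spread)),
    2500, 60000
  ))
  gap <- as.integer(600 + round(rexp(n, 1 / max(1, config$gap_mean - 600))))
  n_ex <- 1L + rpois(n, max(0, config$exons_per_gene - 1))
  second <- runif(n) < config$overlap_frac & len >= 4000
  # sequential placement per chromosome
  start <- integer(n)
  sizes <- numeric(config$n_chroms)
  for (c_i in seq_len(config$n_chroms)) {
    idx <- which(chrom_of == paste0("chr", c_i))
    step <- len[idx] + gap[idx]
    start[idx] <- 3500L + c(0L, cumsum(step[-length(step)]))
    sizes[c_i] <- 3500 + sum(step) + 3500
  }
  end <- start + len
  gene_id <- sprintf("g%05d", seq_len(n))
  # primary transcript exon layouts (loop does cheap vector work only)
  lay1 <- vector("list", n)
  for (i in seq_len(n)) lay1[[i]] <- make_exon_layout(len[i], n_ex[i])
  tx1 <- tibble(
    chrom = chrom_of, start = start, end = end,
    name = paste0(gene_id, ".1"), score = 0, strand = strand,
    exon_starts = purrr::map2(lay1, start, function(l, s) s + l$starts),
    exon_ends = purrr::map2(lay1, start, function(l, s) s + l$ends)
  )
  idx2 <- which(second)
  tx2 <- NULL
  if (length(idx2) > 0) {
    delta <- as.integer(round(len[idx2] * 0.35))
    n_ex2 <- 1L + rpois(length(idx2), 2)
    lay2 <- purrr::map2(len[idx2] - delta, n_ex2, make_exon_layout)
    s2 <- start[idx2] + delta
    tx2 <- tibble(
      chrom = chrom_of[idx2], start = s2, end = end[idx2],
      name = paste0(gene_id[idx2], ".2"), score = 0, strand = strand[idx2],
      exon_starts = purrr::map2(lay2, s2, function(l, s) s + l$starts),
      exon_ends = purrr::map2(lay2, s2, function(l, s) s + l$ends)
    )
  }
  transcripts <- dplyr::bind_rows(tx1, tx2) |>
    dplyr::arrange(.data$chrom, .data$start, .data$name)
  # per-gene exon union (only genes with a second transcript need a merge)
  ex_starts <- tx1$exon_starts
  ex_ends <- tx1$exon_ends
  for (j in seq_along(idx2)) {
    i <- idx2[j]
    r <- IRanges::reduce(as_iranges0(c(ex_starts[[i]], tx2$exon_starts[[j]]),
                                     c(ex_ends[[i]], tx2$exon_ends[[j]])))
    ex_starts[[i]] <- IRanges::start(r) - 1L
    ex_ends[[i]] <- IRanges::end(r)
  }
  list(
    transcripts = transcripts,
    chrom_sizes = tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                         size = sizes),
    genes = tibble(
      gene_id = gene_id, chrom = chrom_of, start = start, end = end,
      strand = strand, tss = ifelse(strand == "-", end - 1L, start),
      n_tx = 1L + as.integer(second),
      exon_starts = ex_starts, exon_ends = ex_ends
    )
  )
}

#' Simulate gene expression
#'
#' Draws log-normal expression per gene and emits a per-transcript table of
#' log2 signal (all transcripts of a gene share its value), emulating
#' exon-array gene summaries keyed by accession.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return A list: `expression` (tibble `id`, `log2_expr`, one row per
#'   transcript) and `gene_expr` (tibble `gene_id`, `E`, `log2_expr`).
#' @export
simulate_expression <- function(config, annotation) {
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  E <- rlnorm(nrow(genes), config$expr_meanlog, config$expr_sdlog)
  gene_expr <- tibble(gene_id = genes$gene_id, E = E, log2_expr = log2(E))
  tx <- annotation$transcripts
  expression <- tibble(
    id = tx$name,
    log2_expr = gene_expr$log2_expr[match(sub("\\..*$", "", tx$name),
                                          gene_expr$gene_id)]
  )
  list(expression = expression, gene_expr = gene_expr)
}

gene_introns <- function(genes) {
  introns_of(genes$gene_id, genes$chrom, genes$start, genes$end,
             genes$exon_starts, genes$exon_ends, id_col = "gene_id")
}

#' Simulate CAGE clusters and Pol2/DHSS tag sets
#'
#' Every gene gets a canonical TSS cluster with tag count proportional to
#' expression. Intronic clusters appear with intensity increasing in
#' expression (`cage_rate`), and their tag counts decay exponentially with
#' the expected local (gene-body) methylation, so intragenic initiation is
#' repressed where methylation is high. Pol2 tags are Poisson with rate
#' `length * pol2_scale * E^pol2_exponent`; DHSS tags use a saturating link.
#' Tags are single-bp 5' positions.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param gene_expr Gene expression truth from [simulate_expression()].
#' @return A list of tibbles: `cage` (`chrom`, `start`, `end`, `name`,
#'   `score` = tag count, `strand`, `type`), `pol2`, `dhss`.
#' @export
simulate_cage_and_tags <- function(config, annotation, gene_expr) {
  set.seed(config$seed + 2L)
  genes <- annotation$genes
  E <- gene_expr$E[match(genes$gene_id, gene_expr$gene_id)]
  w <- config$cluster_width
  half <- (w - 1L) %/% 2L
  # canonical TSS clusters
  canon <- tibble(
    chrom = genes$chrom,
    start = genes$tss - half,
    end = genes$tss + half + 1L,
    name = paste0(genes$gene_id, "_p0"),
    score = 1 + rpois(nrow(genes), config$tss_cluster_scale * E),
    strand = genes$strand,
    type = "canonical"
  )
  # intronic clusters
  introns <- gene_introns(genes)
  intron_split <- split(seq_len(nrow(introns)), introns$gene_id)
  intronic <- purrr::map(seq_len(nrow(genes)), function(i) {
    idx <- intron_split[[genes$gene_id[i]]]
    if (is.null(idx)) return(NULL)
    ii <- introns[idx, , drop = FALSE]
    ok <- (ii$end - ii$start) >= (w + 10L)
    ii <- ii[ok, , drop = FALSE]
    if (nrow(ii) == 0) return(NULL)
    ibp <- sum(ii$end - ii$start)
    lambda <- config$cage_rate * (ibp / 1e4) * E[i] / (E[i] + config$cage_sat)
    k <- rpois(1, lambda)
    if (k == 0) return(NULL)
    pick <- sample.int(nrow(ii), k, replace = TRUE,
                       prob = ii$end - ii$start)
    pos <- as.integer(floor(runif(k, ii$start[pick] + 1,
                                  ii$end[pick] - w - 1)))
    m_true <- body_methylation_mean(E[i], config)
    tibble(
      chrom = genes$chrom[i], start = pos, end = pos + w,
      name = paste0(genes$gene_id[i], "_i", seq_len(k)),
      score = 1 + rpois(k, config$cage_tag_scale *
                          exp(-config$cage_meth_lambda * m_true)),
      strand = genes$strand[i],
      type = "intronic"
    )
  }) |> dplyr::bind_rows()
  len <- genes$end - genes$start
  draw_tags <- function(rate) {
    counts <- rpois(nrow(genes), len * rate)
    gi <- rep.int(seq_len(nrow(genes)), counts)
    pos <- as.integer(floor(runif(length(gi), genes$start[gi], genes$end[gi])))
    tibble(chrom = genes$chrom[gi], start = pos, end = pos + 1L,
           name = ".", score = 0, strand = "+") |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  list(
    cage = dplyr::bind_rows(canon, intronic) |>
      dplyr::arrange(.data$chrom, .data$start),
    pol2 = draw_tags(config$pol2_scale * E^config$pol2_exponent),
    dhss = draw_tags(config$dhss_scale * E / (E + config$dhss_k))
  )
}

#' Simulate the methylome
#'
#' CpG records are placed at roughly `cpg_spacing` bp genome-wide. Their
#' expected percent methylation depends on position: the gene body follows
#' the accessibility-interference model `M(E)`, the promoter zone (TSS-3kb to
#' TSS+1kb in transcription orientation) follows the logistic promoter decay,
#' and intergenic positions sit at a low baseline. Three extra CpGs are
#' planted symmetrically around every CAGE cluster midpoint (clusters are
#' CpG-rich) with the value of their zone. Gaussian noise of sd `noise_sd` is
#' added and values are clamped to [0, 100].
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param gene_expr Gene expression truth.
#' @param cage CAGE cluster tibble from [simulate_cage_and_tags()] (may be
#'   `NULL` to skip cluster CpGs).
#' @return A methylation tibble (`chrom`, `start`, `end`, `percent`,
#'   `coverage`).
#' @export
simulate_methylome <- function(config, annotation, gene_expr, cage = NULL) {
  set.seed(config$seed + 3L)
  genes <- annotation$genes
  E <- gene_expr$E[match(genes$gene_id, gene_expr$gene_id)]
  m_body <- body_methylation_mean(E, config)
  m_tss <- tss_methylation_mean(E, config)
  sizes <- annotation$chrom_sizes
  pos_list <- purrr::map2(sizes$chrom, sizes$size, function(ch, sz) {
    grid <- seq.int(200L, as.integer(sz) - 200L, by = config$cpg_spacing)
    jit <- as.integer(floor(runif(length(grid), 0, config$cpg_spacing / 2)))
    tibble(chrom = ch, pos = grid + jit)
  })
  cp <- dplyr::bind_rows(pos_list)
  # zone classification
  mean_val <- rep(config$intergenic_meth, nrow(cp))
  gene_i <- rep(NA_integer_, nrow(cp))
  for (ch in unique(cp$chrom)) {
    rows <- which(cp$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) next
    gi <- gi[order(genes$start[gi])]
    slot <- findInterval(cp$pos[rows], genes$start[gi])
    inside <- slot > 0 & cp$pos[rows] < genes$end[gi][pmax(slot, 1)]
    gene_i[rows[inside]] <- gi[slot[inside]]
  }
  genic <- !is.na(gene_i)
  gidx <- gene_i[genic]
  off <- ifelse(genes$strand[gidx] == "-",
                genes$end[gidx] - 1L - cp$pos[genic],
                cp$pos[genic] - genes$start[gidx])
  mean_val[genic] <- ifelse(off < 1000, m_tss[gidx], m_body[gidx])
  # upstream promoter zones over intergenic positions
  up <- 3000L
  zones <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "-", genes$end, genes$start - up),
    end = ifelse(genes$strand == "-", genes$end + up, genes$start),
    gene = seq_len(nrow(genes)),
    tss = genes$tss
  )
  zones$start <- pmax(zones$start, 0)
  inter_rows <- which(!genic)
  hits <- point_in_rows(tibble(chrom = cp$chrom[inter_rows],
                               pos = cp$pos[inter_rows]), zones)
  if (nrow(hits) > 0) {
    hits$dist <- abs(cp$pos[inter_rows[hits$qrow]] - zones$tss[hits$srow])
    best <- hits |>
      dplyr::group_by(.data$qrow) |>
      dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    mean_val[inter_rows[best$qrow]] <- m_tss[zones$gene[best$srow]]
  }
  cp$mean_val <- mean_val
  # cluster CpGs (clusters are CpG-rich); zone value of the midpoint
  if (!is.null(cage) && nrow(cage) > 0) {
    gi <- match(sub("_(p0|i[0-9]+)$", "", cage$name), genes$gene_id)
    mid <- cage$start + (cage$end - cage$start - 1L) %/% 2L
    val <- ifelse(cage$type == "canonical", m_tss[gi], m_body[gi])
    extra <- tibble(
      chrom = rep(cage$chrom, each = 3L),
      pos = as.integer(rep(mid, each = 3L) + c(-10L, 0L, 10L)),
      mean_val = rep(val, each = 3L)
    )
    cp <- dplyr::bind_rows(cp, extra)
  }
  cp <- dplyr::distinct(cp, .data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos)
  percent <- clip01(cp$mean_val + rnorm(nrow(cp), 0, config$noise_sd), 0, 100)
  tibble(
    chrom = cp$chrom, start = cp$pos, end = cp$pos + 1L,
    percent = percent,
    coverage = 3L + rpois(nrow(cp), 15)
  )
}

#' Simulate a complete dataset
#'
#' Runs all generator stages in order under a single seed and bundles the
#' results with the per-gene truth table.
#'
#' @param config A [sim_config()].
#' @return An object of class `gb_sim`: list with `transcripts`,
#'   `chrom_sizes`, `expression`, `methylome`, `cage`, `pol2`, `dhss`,
#'   `truth`, `genes`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  ex <- simulate_expression(config, ann)
  tags <- simulate_cage_and_tags(config, ann, ex$gene_expr)
  meth <- simulate_methylome(config, ann, ex$gene_expr, tags$cage)
  g <- ann$genes
  E <- ex$gene_expr$E
  truth <- tibble(
    gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
    strand = g$strand, length = g$end - g$start,
    E = E, log2_expr = log2(E),
    m_body = body_methylation_mean(E, config),
    m_tss = tss_methylation_mean(E, config),
    pol2_rate = config$pol2_scale * E^config$pol2_exponent,
    dhss_rate = config$dhss_scale * E / (E + config$dhss_k)
  )
  structure(
    list(transcripts = ann$transcripts, chrom_sizes = ann$chrom_sizes,
         expression = ex$expression, methylome = meth,
         cage = tags$cage, pol2 = tags$pol2, dhss = tags$dhss,
         truth = truth, genes = ann$genes, config = config),
    class = "gb_sim"
  )
}

#' @export
print.gb_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$genes), "genes,",
      nrow(x$methylome), "CpGs,", nrow(x$cage), "CAGE clusters,",
      nrow(x$pol2), "Pol2 tags,", nrow(x$dhss), "DHSS tags",
      "(seed", x$config$seed, ")\n")
  invisible(x)
}

sim_header <- function(config) {
  sprintf("seed=%d config_hash=%s", config$seed, rlang::hash(unclass(config)))
}

#' Write a simulated dataset to a directory
#'
#' Emits `transcripts.bed12`, `sizes.tsv`, `meth.tsv`, `expr.tsv`,
#' `cage.bed`, `pol2.bed`, `dhss.bed` and `truth.tsv`; every file carries the
#' seed and a config hash in a header comment. All files round-trip through
#' the package's readers.
#'
#' @param sim A `gb_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- sim_header(sim$config)
  p <- function(f) file.path(dir, f)
  write_transcripts(sim$transcripts, p("transcripts.bed12"), header = h)
  write_chrom_sizes(sim$chrom_sizes, p("sizes.tsv"), header = h)
  write_methylation(sim$methylome, p("meth.tsv"), header = h)
  write_expression(sim$expression, p("expr.tsv"), header = h)
  write_bed6(dplyr::mutate(sim$cage, score = .data$score), p("cage.bed"),
             header = h)
  write_bed6(sim$pol2, p("pol2.bed"), header = h)
  write_bed6(sim$dhss, p("dhss.bed"), header = h)
  write_tsv_with_header(sim$truth[, setdiff(names(sim$truth), c("exon_starts", "exon_ends"))],
                        p("truth.tsv"), h, col_names = TRUE)
  invisible(dir)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir Directory written by [write_sim_dataset()].
#' @return A list with the same tabular elements as a `gb_sim` object
#'   (without `genes`/`config`).
#' @export
read_sim_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    transcripts = read_transcripts(p("transcripts.bed12")),
    chrom_sizes = read_chrom_sizes(p("sizes.tsv")),
    methylome = read_methylation(p("meth.tsv")),
    expression = read_expression(p("expr.tsv")),
    cage = read_bed(p("cage.bed")),
    pol2 = read_bed(p("pol2.bed")),
    dhss = read_bed(p("dhss.bed")),
    truth = readr::read_tsv(p("truth.tsv"), comment = "#",
                            show_col_types = FALSE, progress = FALSE)
  )
}

mirror_intervals <- function(df, sizes) {
  L <- sizes$size[match(df$chrom, sizes$chrom)]
  out <- df
  out$start <- as.integer(L - df$end)
  out$end <- as.integer(L - df$start)
  if ("strand" %in% names(df)) {
    out$strand <- dplyr::case_match(df$strand, "+" ~ "-", "-" ~ "+",
                                    .default = df$strand)
  }
  out
}

#' Mirror a dataset's coordinates and swap strands
#'
#' Maps every coordinate x to `chrom_size - x` and flips strands, producing a
#' genome read in the opposite direction. Every orientation-aware summary
#' statistic of the pipeline is invariant under this transformation, and
#' metagene profiles are preserved in transcription orientation.
#'
#' @param data A `gb_sim` object or compatible list of tables.
#' @return The mirrored dataset (same shape).
#' @export
mirror_dataset <- function(data) {
  sizes <- data$chrom_sizes
  out <- data
  tx <- mirror_intervals(data$transcripts, sizes)
  L <- sizes$size[match(data$transcripts$chrom, sizes$chrom)]
  tx$exon_starts <- purrr::pmap(
    list(data$transcripts$exon_ends, L),
    function(ee, l) as.integer(l - rev(ee))
  )
  tx$exon_ends <- purrr::pmap(
    list(data$transcripts$exon_starts, L),
    function(es, l) as.integer(l - rev(es))
  )
  out$transcripts <- tx
  for (nm in intersect(c("methylome", "cage", "pol2", "dhss"), names(data))) {
    if (!is.null(data[[nm]])) out[[nm]] <- mirror_intervals(data[[nm]], sizes)
  }
  out
}
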