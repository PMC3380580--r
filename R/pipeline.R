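# End-to-end orchestration: from transcripts + assay tables to the full set
# of methylation/expression/chromatin analyses and a machine-readable
# summary.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

cluster_uid <- function(clusters) {
  if ("name" %in% names(clusters) && !anyNA(clusters$name) &&
      !any(duplicated(clusters$name))) {
    clusters$name
  } else {
    paste(clusters$chrom, clusters$start, clusters$end, sep = ":")
  }
}

#' Map a per-accession expression table onto merged loci
#'
#' Locus expression is the mean log2 signal of its member accessions that
#' appear in the expression table.
#'
#' @param loci Locus tibble from [merge_transcripts()].
#' @param expression Expression tibble (`id`, `log2_expr`).
#' @return A tibble `locus_id`, `log2_expr`, `n_ids` (loci with no expressed
#'   member get `NA`).
#' @export
locus_expression <- function(loci, expression) {
  loci[, c("locus_id", "members")] |>
    tidyr::unnest("members") |>
    dplyr::left_join(expression, by = c(members = "id")) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_ids = sum(!is.na(.data$log2_expr)),
      log2_expr = if (all(is.na(.data$log2_expr))) NA_real_
                  else mean(.data$log2_expr, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select("locus_id", "log2_expr", "n_ids")
}

#' Split genes at an expression quantile and compare group means
#'
#' Genes are split at the `split` quantile of expression (stably, by value
#' then id); per-group mean and standard error of gene-body methylation and
#' intronic CAGE level are reported.
#'
#' @param df Data frame with one row per gene.
#' @param expr,body_meth,intronic_cage Columns (tidy-eval).
#' @param split Quantile at which to cut (default median).
#' @param id Tie-break identifier column.
#' @return A tibble with rows `low` and `high`.
#' @export
compare_low_high <- function(df, expr, body_meth, intronic_cage,
                             split = 0.5, id = NULL) {
  e <- dplyr::pull(df, {{ expr }})
  if (length(unique(e)) < 2) abort("degenerate split: constant expression")
  id_quo <- rlang::enquo(id)
  ids <- if (rlang::quo_is_null(id_quo)) {
    if ("locus_id" %in% names(df)) df$locus_id else df[[1]]
  } else {
    dplyr::pull(df, {{ id }})
  }
  ord <- order(e, ids, method = "radix")
  n_low <- floor(nrow(df) * split)
  if (n_low < 2 || nrow(df) - n_low < 2) abort("each group needs >= 2 genes")
  grp <- character(nrow(df))
  grp[ord] <- rep(c("low", "high"), c(n_low, nrow(df) - n_low))
  m <- dplyr::pull(df, {{ body_meth }})
  cg <- dplyr::pull(df, {{ intronic_cage }})
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  }
  tibble(group = c("low", "high")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = sum(grp == .data$group),
      mean_expr = mean(e[grp == .data$group]),
      mean_meth = mean(m[grp == .data$group], na.rm = TRUE),
      se_meth = se(m[grp == .data$group]),
      mean_intronic_cage = mean(cg[grp == .data$group], na.rm = TRUE),
      se_intronic_cage = se(cg[grp == .data$group])
    ) |>
    dplyr::ungroup()
}

binreg_or_null <- function(df, x, y, k, what, id = NULL) {
  n_ok <- sum(stats::complete.cases(
    dplyr::pull(df, {{ x }}), dplyr::pull(df, {{ y }})))
  k_use <- max(3L, min(k, n_ok %/% 2L))
  if (n_ok < 6) {
    warn(paste0(what, ": too few observations, skipped"))
    return(NULL)
  }
  bin_regress(df, {{ x }}, {{ y }}, k = k_use, id = {{ id }})
}

#' Run the full meta-analysis
#'
#' Executes every pipeline stage on a dataset (in-memory tables, e.g. a
#' `gb_sim` object or the output of [read_sim_dataset()]): locus merging,
#' quintile metagene profile, 100-bin gene-body methylation regression (plus
#' a length-stratified version), promoter methylation versus CAGE activity
#' for intronic and canonical promoters, the intron initiation/silent-site
#' partition and its cross-class regression, the genic/intergenic summary,
#' Pol2 and DHSS density versus expression, and the joint
#' methylation/intronic-expression table with a low/high expression group
#' comparison. Stages needing CAGE (or Pol2/DHSS) input are skipped with a
#' warning when it is absent.
#'
#' @param data Named list with `transcripts`, `chrom_sizes`, `expression`,
#'   `methylome`, and optionally `cage`, `pol2`, `dhss`.
#' @param bins Number of expression/methylation bins for the regressions.
#' @param quintiles Number of bins for the metagene profile.
#' @param window Metagene window size (bp).
#' @param body_trim Gene-body trim (bp) at each end.
#' @param tss_up,tss_down,tts_up,tts_down Metagene flank extents (bp).
#' @param strand_aware Strand-aware locus merging.
#' @param denominator Intronic CAGE level denominator (`"intron"` or
#'   `"locus"`).
#' @param min_coverage Minimum CpG coverage.
#' @param split Expression quantile for the low/high comparison.
#' @param length_fraction Stratum fraction for the length-stratified check.
#' @return An object of class `gb_run`: a list of per-stage results plus a
#'   `summary` tibble with every correlation (`analysis`, `r`, `p`,
#'   `n_bins`, `peak_bin`) and scalar summaries, and `params`.
#' @export
run_all <- function(data, bins = 100, quintiles = 5, window = 100,
                    body_trim = 1000, tss_up = 3000, tss_down = 5000,
                    tts_up = 5000, tts_down = 3000, strand_aware = TRUE,
                    denominator = c("intron", "locus"), min_coverage = 1,
                    split = 0.5, length_fraction = 0.2) {
  denominator <- match.arg(denominator)
  has_cage <- !is.null(data$cage) && nrow(data$cage) > 0
  if (!has_cage) warn("no CAGE input: promoter/intron-partition/joint stages skipped")

  loci <- run_stage("merge", merge_transcripts(data$transcripts,
                                               strand_aware = strand_aware))
  regions <- run_stage("regions", derive_regions(
    loci, chrom_sizes = data$chrom_sizes, body_trim = body_trim,
    tss_up = tss_up, tss_down = tss_down, tts_up = tts_up, tts_down = tts_down))
  introns <- run_stage("regions", locus_introns(loci))
  expr <- run_stage("expression", locus_expression(loci, data$expression))

  cpgs <- filter_coverage(data$methylome, min_coverage)
  per_gene <- run_stage("methylation", {
    body <- regions[!is.na(regions$body_start), , drop = FALSE]
    body_m <- region_methylation(
      cpgs, tibble(chrom = body$chrom, start = body$body_start,
                   end = body$body_end, locus_id = body$locus_id),
      by = "locus_id")
    prom_m <- region_methylation(
      cpgs, tibble(chrom = regions$chrom, start = regions$promoter_start,
                   end = regions$promoter_end, locus_id = regions$locus_id),
      by = "locus_id")
    expr |>
      dplyr::left_join(dplyr::rename(body_m, body_meth = "mean_percent",
                                     body_n_cpg = "n_sites"),
                       by = "locus_id") |>
      dplyr::left_join(dplyr::rename(prom_m, promoter_meth = "mean_percent",
                                     promoter_n_cpg = "n_sites"),
                       by = "locus_id") |>
      dplyr::left_join(regions[, c("locus_id", "length")], by = "locus_id")
  })
  usable <- per_gene[!is.na(per_gene$log2_expr), , drop = FALSE]

  qbins <- run_stage("metagene",
                     quantile_bins(usable, .data$log2_expr, k = quintiles))
  metagene <- run_stage("metagene", metagene_profile(
    cpgs, regions, qbins[, c("locus_id", "bin")], window = window,
    tss_up = tss_up, tss_down = tss_down, tts_up = tts_up,
    tts_down = tts_down))

  body_reg <- run_stage("body_regression", binreg_or_null(
    usable, .data$log2_expr, .data$body_meth, bins, "body regression"))
  tss_reg <- run_stage("tss_regression", binreg_or_null(
    usable, .data$log2_expr, .data$promoter_meth, bins, "TSS regression"))
  strata <- run_stage("length_strata", {
    ok <- usable[!is.na(usable$body_meth), , drop = FALSE]
    if (nrow(ok) >= 50) {
      length_stratified(ok, .data$length, .data$log2_expr, .data$body_meth,
                        fraction = length_fraction)
    } else NULL
  })

  promoters <- NULL
  partition <- NULL
  class_reg <- NULL
  joint <- NULL
  low_high <- NULL
  icage <- NULL
  if (has_cage) {
    clusters <- run_stage("cage", cage_activity(data$cage))
    promoters <- run_stage("promoters", {
      intr <- intronic_clusters(clusters, introns)
      intr_m <- region_methylation(
        cpgs, dplyr::mutate(intr, cid = dplyr::row_number()), by = "cid")
      intr$meth <- intr_m$mean_percent[match(seq_len(nrow(intr)), intr_m$cid)]
      canon_win <- tibble(chrom = regions$chrom,
                          start = pmax(regions$tss - 500L, 0L),
                          end = regions$tss + 501L,
                          locus_id = regions$locus_id)
      hits <- point_in_rows(tibble(chrom = clusters$chrom,
                                   pos = clusters$midpoint), canon_win)
      canon <- clusters[unique(hits$qrow), , drop = FALSE]
      canon_m <- region_methylation(
        cpgs, dplyr::mutate(canon, cid = dplyr::row_number()), by = "cid")
      canon$meth <- canon_m$mean_percent[match(seq_len(nrow(canon)),
                                               canon_m$cid)]
      list(
        intronic = intr,
        canonical = canon,
        # a stable per-cluster id breaks activity ties reproducibly
        intronic_reg = binreg_or_null(
          dplyr::mutate(intr, cl_id = cluster_uid(intr)),
          .data$activity, .data$meth, bins,
          "intronic promoter regression", id = .data$cl_id),
        canonical_reg = binreg_or_null(
          dplyr::mutate(canon, cl_id = cluster_uid(canon)),
          .data$activity, .data$meth, bins,
          "canonical promoter regression", id = .data$cl_id)
      )
    })
    partition <- run_stage("intron_partition", {
      part <- partition_introns(introns, clusters)
      summ <- partition_summary(part)
      cls <- purrr::map(c("initiation", "silent"), function(cl) {
        sub <- part[part$class == cl, , drop = FALSE]
        region_methylation(cpgs, sub, by = "locus_id") |>
          stats::setNames(c("locus_id", paste0("meth_", cl),
                            paste0("n_", cl)))
      })
      meth_cls <- Reduce(function(a, b) dplyr::full_join(a, b, by = "locus_id"),
                         cls)
      list(intervals = part, summary = summ, class_methylation = meth_cls)
    })
    class_reg <- run_stage("intron_partition", binreg_or_null(
      partition$class_methylation |>
        dplyr::filter(!is.na(.data$meth_silent) & !is.na(.data$meth_initiation)),
      .data$meth_silent, .data$meth_initiation, bins,
      "initiation vs silent regression"))
    icage <- run_stage("intronic_cage", intronic_cage_level(
      clusters, loci, denominator = denominator))
    per_gene <- dplyr::left_join(
      per_gene, dplyr::rename(icage[, c("locus_id", "level")],
                              intronic_cage = "level"), by = "locus_id")
    usable <- per_gene[!is.na(per_gene$log2_expr), , drop = FALSE]
    joint <- run_stage("joint", {
      b <- quantile_bins(usable, .data$log2_expr, k = min(bins, nrow(usable) %/% 2))
      dplyr::full_join(
        bin_aggregate(b, .data$log2_expr, .data$body_meth) |>
          dplyr::rename(mean_log2_expr = "mean_x", mean_body_meth = "mean_y",
                        n_meth = "n_y"),
        bin_aggregate(b, .data$log2_expr, .data$intronic_cage) |>
          dplyr::select("bin", mean_intronic_cage = "mean_y",
                        n_cage = "n_y"),
        by = "bin")
    })
    low_high <- run_stage("low_high", compare_low_high(
      usable, .data$log2_expr, .data$body_meth, .data$intronic_cage,
      split = split))
  }

  gi <- run_stage("genic_intergenic",
                  genic_vs_intergenic(cpgs, loci, data$chrom_sizes))

  pol2_reg <- NULL
  dhss_reg <- NULL
  densities <- list()
  for (assay in c("pol2", "dhss")) {
    if (is.null(data[[assay]]) || nrow(data[[assay]]) == 0) {
      warn(paste0("no ", assay, " input: density stage skipped"))
      next
    }
    d <- run_stage(paste0(assay, "_density"),
                   locus_tag_density(data[[assay]], loci))
    densities[[assay]] <- d
    df <- dplyr::left_join(usable, stats::setNames(
      d[, c("locus_id", "density")], c("locus_id", "density")),
      by = "locus_id")
    reg <- run_stage(paste0(assay, "_density"), binreg_or_null(
      df, .data$log2_expr, .data$density, bins,
      paste0(assay, " density regression")))
    if (assay == "pol2") pol2_reg <- reg else dhss_reg <- reg
  }

  regs <- list(
    body_meth_vs_expr = body_reg,
    tss_meth_vs_expr = tss_reg,
    body_meth_vs_expr_short = if (!is.null(strata)) strata$short,
    body_meth_vs_expr_long = if (!is.null(strata)) strata$long,
    intronic_promoter_meth_vs_activity =
      if (!is.null(promoters)) promoters$intronic_reg,
    canonical_promoter_meth_vs_activity =
      if (!is.null(promoters)) promoters$canonical_reg,
    initiation_vs_silent_meth = class_reg,
    pol2_density_vs_expr = pol2_reg,
    dhss_density_vs_expr = dhss_reg
  )
  summary <- purrr::imap(regs, function(r, nm) {
    if (is.null(r)) return(NULL)
    g <- glance(r)
    tibble(analysis = nm, r = g$r, p = g$p, n_bins = g$n_bins,
           peak_bin = g$peak_bin, k = g$k, r_raw = g$r_raw)
  }) |> dplyr::bind_rows()

  structure(
    list(
      loci = loci, regions = regions, introns = introns,
      per_gene = per_gene, metagene = metagene,
      body_regression = body_reg, tss_regression = tss_reg,
      length_strata = strata, promoters = promoters,
      intron_partition = partition, initiation_vs_silent = class_reg,
      intronic_cage = icage, genic_intergenic = gi,
      densities = densities, pol2_regression = pol2_reg,
      dhss_regression = dhss_reg, joint = joint, low_high = low_high,
      summary = summary,
      params = list(bins = bins, quintiles = quintiles, window = window,
                    body_trim = body_trim, tss_up = tss_up,
                    tss_down = tss_down, tts_up = tts_up,
                    tts_down = tts_down, strand_aware = strand_aware,
                    denominator = denominator, min_coverage = min_coverage,
                    split = split, length_fraction = length_fraction)
    ),
    class = "gb_run"
  )
}

#' @export
print.gb_run <- function(x, ...) {
  cat("Gene-body methylation meta-analysis:", nrow(x$loci), "loci\n\n")
  print(x$summary)
  gi <- x$genic_intergenic
  cat(sprintf("\nGenic %.1f%% vs intergenic %.1f%% methylation\n",
              gi$mean_percent[gi$class == "genic"],
              gi$mean_percent[gi$class == "intergenic"]))
  invisible(x)
}

#' Machine-readable run summary
#'
#' Flattens a pipeline run into a named list of scalar results (every
#' regression's r/p/n/peak bin, genic and intergenic means, mean initiation
#' fraction, low/high group means) suitable for JSON export.
#'
#' @param run A `gb_run` object.
#' @return A named list of scalars.
#' @export
run_summary <- function(run) {
  out <- list()
  for (i in seq_len(nrow(run$summary))) {
    s <- run$summary[i, ]
    out[[s$analysis]] <- list(r = s$r, p = s$p, n_bins = s$n_bins,
                              peak_bin = s$peak_bin, r_raw = s$r_raw)
  }
  gi <- run$genic_intergenic
  out$genic_mean_meth <- gi$mean_percent[gi$class == "genic"]
  out$intergenic_mean_meth <- gi$mean_percent[gi$class == "intergenic"]
  if (!is.null(run$intron_partition)) {
    out$mean_fraction_initiation <-
      mean(run$intron_partition$summary$fraction_initiation, na.rm = TRUE)
  }
  if (!is.null(run$low_high)) {
    lh <- run$low_high
    out$low_expr_mean_meth <- lh$mean_meth[lh$group == "low"]
    out$high_expr_mean_meth <- lh$mean_meth[lh$group == "high"]
    out$low_expr_mean_intronic_cage <- lh$mean_intronic_cage[lh$group == "low"]
    out$high_expr_mean_intronic_cage <- lh$mean_intronic_cage[lh$group == "high"]
  }
  out$n_loci <- nrow(run$loci)
  out
}

#' Write the run summary as JSON
#'
#' @param run A `gb_run` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  jsonlite::write_json(run_summary(run), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
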