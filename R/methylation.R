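# Aggregation of per-CpG percent methylation over interval sets, metagene
# window profiles anchored at the TSS/TTS, and the genic/intergenic summary.

filter_coverage <- function(cpgs, min_coverage) {
  if (min_coverage > 1 && "coverage" %in% names(cpgs)) {
    cpgs[cpgs$coverage >= min_coverage, , drop = FALSE]
  } else {
    cpgs
  }
}

#' Mean percent methylation over a region set
#'
#' The unweighted mean of the percent methylation of all covered CpGs whose
#' position (record start) lies in any of the regions. Read coverage is not
#' used as a weight; a CpG falling in several overlapping regions of the same
#' group is counted once. Regions with no covered CpG yield `NA`.
#'
#' @param cpgs Methylation tibble (see [read_methylation()]).
#' @param regions Interval tibble (`chrom`, `start`, `end`).
#' @param by Optional name of a column of `regions` to aggregate by (e.g.
#'   `"locus_id"`); with `NULL` all regions form a single set.
#' @param min_coverage Drop CpGs with coverage below this (default 1 = off).
#' @return With `by = NULL`, a one-row tibble `mean_percent`, `n_sites`;
#'   otherwise one row per group (groups without CpGs get `NA`/0).
#' @export
region_methylation <- function(cpgs, regions, by = NULL, min_coverage = 1) {
  check_intervals(regions, "region table")
  cpgs <- filter_coverage(cpgs, min_coverage)
  hits <- point_in_rows(tibble(chrom = cpgs$chrom, pos = cpgs$start), regions)
  if (is.null(by)) {
    idx <- unique(hits$qrow)
    return(tibble(
      mean_percent = if (length(idx) == 0) NA_real_ else mean(cpgs$percent[idx]),
      n_sites = length(idx)
    ))
  }
  if (!by %in% names(regions)) abort(paste0("no column '", by, "' in regions"))
  groups <- unique(regions[[by]])
  agg <- tibble(grp = regions[[by]][hits$srow], qrow = hits$qrow) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(mean_percent = mean(cpgs$percent[.data$qrow]),
                     n_sites = dplyr::n(), .groups = "drop")
  out <- tibble(grp = groups) |>
    dplyr::left_join(agg, by = "grp") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  names(out)[1] <- by
  out
}

metagene_offsets <- function(up, down, window) {
  seq.int(-up, down - window, by = window)
}

#' Metagene methylation profile around TSS and TTS
#'
#' For each locus, fixed-size windows are laid out in transcription
#' orientation relative to the TSS (`-tss_up .. +tss_down`) and the TTS
#' (`-tts_up .. +tts_down`); each window's mean CpG methylation is computed
#' per gene, then averaged (gene-weighted, missing windows dropped) within
#' each expression bin. Per-bin region summaries (promoter-proximal window,
#' gene body, TTS-proximal window) with standard errors are also returned.
#'
#' @param cpgs Methylation tibble.
#' @param regions Region tibble from [derive_regions()].
#' @param bins Tibble with `locus_id`, `bin` assigning each locus to one bin
#'   (e.g. from [quantile_bins()]).
#' @param window Window width in bp.
#' @param tss_up,tss_down,tts_up,tts_down Profile extent in bp.
#' @param min_coverage Minimum CpG coverage.
#' @return An object of class `gb_metagene`: list with `profile` (tibble
#'   `bin`, `anchor`, `offset`, `mean_percent`, `n_genes`) and
#'   `region_summary` (tibble `bin`, `region`, `mean_percent`, `se`,
#'   `n_genes`).
#' @export
metagene_profile <- function(cpgs, regions, bins, window = 100,
                             tss_up = 3000, tss_down = 5000,
                             tts_up = 5000, tts_down = 3000,
                             min_coverage = 1) {
  cpgs <- filter_coverage(cpgs, min_coverage)
  if (!all(c("locus_id", "bin") %in% names(bins))) {
    abort("bins must have columns locus_id, bin")
  }
  reg <- dplyr::inner_join(regions, bins[, c("locus_id", "bin")], by = "locus_id")
  if (any(!regions$locus_id %in% bins$locus_id)) {
    warn("some loci have no bin assignment and are dropped from the profile")
  }
  wins <- purrr::map2(
    c("TSS", "TTS"),
    list(metagene_offsets(tss_up, tss_down, window),
         metagene_offsets(tts_up, tts_down, window)),
    function(anchor, offsets) {
      a <- if (anchor == "TSS") reg$tss else reg$tts
      g <- tidyr::expand_grid(i = seq_len(nrow(reg)), offset = offsets)
      w <- oriented_window(a[g$i] + 0, reg$strand[g$i], -g$offset,
                           g$offset + window)
      tibble(chrom = reg$chrom[g$i], start = pmax(w$start, 0), end = w$end,
             locus_id = reg$locus_id[g$i], bin = reg$bin[g$i],
             anchor = anchor, offset = g$offset)
    }
  ) |> dplyr::bind_rows()
  wins <- wins[wins$end > wins$start, , drop = FALSE]
  hits <- point_in_rows(tibble(chrom = cpgs$chrom, pos = cpgs$start), wins)
  per_gene <- tibble(
    bin = wins$bin[hits$srow], anchor = wins$anchor[hits$srow],
    offset = wins$offset[hits$srow], locus_id = wins$locus_id[hits$srow],
    percent = cpgs$percent[hits$qrow]
  ) |>
    dplyr::group_by(.data$bin, .data$anchor, .data$offset, .data$locus_id) |>
    dplyr::summarise(gene_mean = mean(.data$percent), .groups = "drop")
  grid <- tidyr::expand_grid(
    bin = sort(unique(bins$bin)), anchor = c("TSS", "TTS"),
    offset = sort(unique(wins$offset))
  )
  grid <- grid[(grid$anchor == "TSS" &
                  grid$offset %in% metagene_offsets(tss_up, tss_down, window)) |
               (grid$anchor == "TTS" &
                  grid$offset %in% metagene_offsets(tts_up, tts_down, window)), ]
  profile <- per_gene |>
    dplyr::group_by(.data$bin, .data$anchor, .data$offset) |>
    dplyr::summarise(mean_percent = mean(.data$gene_mean),
                     n_genes = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(grid, by = c("bin", "anchor", "offset")) |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) |>
    dplyr::arrange(.data$bin, .data$anchor, .data$offset)
  region_summary <- purrr::map(
    list(c("promoter", "TSS region"), c("body", "gene body"),
         c("tts_region", "TTS region")),
    function(spec) {
      pre <- spec[1]
      s <- if (pre == "body") reg$body_start else reg[[paste0(pre, "_start")]]
      e <- if (pre == "body") reg$body_end else reg[[paste0(pre, "_end")]]
      keep <- !is.na(s) & !is.na(e) & e > s
      rm <- region_methylation(
        cpgs,
        tibble(chrom = reg$chrom[keep], start = s[keep], end = e[keep],
               locus_id = reg$locus_id[keep]),
        by = "locus_id"
      )
      rm |>
        dplyr::inner_join(reg[, c("locus_id", "bin")], by = "locus_id") |>
        dplyr::filter(!is.na(.data$mean_percent)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          region = spec[2],
          se = sd(.data$mean_percent) / sqrt(dplyr::n()),
          mean_percent = mean(.data$mean_percent),
          n_genes = dplyr::n(), .groups = "drop"
        )
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::select("bin", "region", "mean_percent", "se", "n_genes") |>
    dplyr::arrange(.data$bin, .data$region)
  structure(
    list(profile = profile, region_summary = region_summary,
         window = window,
         extent = c(tss_up = tss_up, tss_down = tss_down,
                    tts_up = tts_up, tts_down = tts_down)),
    class = "gb_metagene"
  )
}

#' @export
print.gb_metagene <- function(x, ...) {
  cat("Metagene methylation profile:",
      length(unique(x$profile$bin)), "bins,",
      x$window, "bp windows\n")
  print(x$region_summary)
  invisible(x)
}

#' Genic versus intergenic methylation
#'
#' Classifies every covered CpG as genic (inside any locus span) or
#' intergenic and reports the mean and standard error of percent methylation
#' per class.
#'
#' @param cpgs Methylation tibble.
#' @param loci Locus tibble.
#' @param chrom_sizes Optional sizes tibble; when given, CpGs are checked to
#'   lie within chromosome bounds.
#' @param min_coverage Minimum CpG coverage.
#' @return A tibble with rows `genic` and `intergenic`: `class`,
#'   `mean_percent`, `se`, `n_sites`.
#' @export
genic_vs_intergenic <- function(cpgs, loci, chrom_sizes = NULL,
                                min_coverage = 1) {
  cpgs <- filter_coverage(cpgs, min_coverage)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes$size[match(cpgs$chrom, chrom_sizes$chrom)]
    if (anyNA(sz) || any(cpgs$start >= sz)) {
      abort("CpG record outside chromosome bounds")
    }
  }
  hits <- point_in_rows(tibble(chrom = cpgs$chrom, pos = cpgs$start),
                        loci[, c("chrom", "start", "end")])
  genic <- rep(FALSE, nrow(cpgs))
  genic[unique(hits$qrow)] <- TRUE
  tibble(class = c("genic", "intergenic"), keep = list(genic, !genic)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      mean_percent = if (sum(.data$keep) == 0) NA_real_
                     else mean(cpgs$percent[.data$keep]),
      se = if (sum(.data$keep) < 2) NA_real_
           else sd(cpgs$percent[.data$keep]) / sqrt(sum(.data$keep)),
      n_sites = sum(.data$keep)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"keep")
}
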