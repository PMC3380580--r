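# Tag densities (Pol2 ChIP-seq, DNase I HS), CAGE promoter activity, and the
# intronic initiation / non-initiation site partition.

#' Tag density over a region set
#'
#' The number of tags whose start position falls in the union of the regions,
#' divided by the union's length in bp (tags per bp). Each tag is counted at
#' most once.
#'
#' @param tags Tag tibble (`chrom`, `start`, `end`); the 5' tag position is
#'   the record start.
#' @param regions Interval tibble.
#' @return Tags per bp (double scalar).
#' @export
tag_density <- function(tags, regions) {
  check_intervals(regions, "region table")
  u <- reduce_intervals(regions)
  bp <- total_bp(u)
  if (bp == 0) abort("region set has zero length")
  hits <- point_in_rows(tibble(chrom = tags$chrom, pos = tags$start), u)
  length(unique(hits$qrow)) / bp
}

#' Per-locus tag density
#'
#' Applies the tag-density formula locus by locus: tags starting within the
#' locus span divided by locus length.
#'
#' @param tags Tag tibble.
#' @param loci Locus tibble.
#' @return A tibble `locus_id`, `n_tags`, `density`.
#' @export
locus_tag_density <- function(tags, loci) {
  hits <- point_in_rows(tibble(chrom = tags$chrom, pos = tags$start),
                        loci[, c("chrom", "start", "end")])
  counts <- tibble(srow = hits$srow) |>
    dplyr::count(.data$srow, name = "n_tags")
  n <- integer(nrow(loci))
  n[counts$srow] <- counts$n_tags
  tibble(locus_id = loci$locus_id, n_tags = n,
         density = n / (loci$end - loci$start))
}

#' CAGE promoter activity
#'
#' Promoter expression level of a tag cluster: tag count divided by cluster
#' length (tags per bp). The cluster midpoint used for intron assignment is
#' also added.
#'
#' @param clusters CAGE cluster tibble (`chrom`, `start`, `end`, `score` =
#'   tag count).
#' @return The input with `tag_count`, `activity` and `midpoint` columns.
#' @export
cage_activity <- function(clusters) {
  check_intervals(clusters, "cluster table")
  if (!"score" %in% names(clusters)) abort("clusters need a score (tag count) column")
  dplyr::mutate(
    clusters,
    tag_count = .data$score,
    activity = .data$score / (.data$end - .data$start),
    midpoint = .data$start + (.data$end - .data$start - 1L) %/% 2L
  )
}

#' Assign CAGE clusters to introns
#'
#' A cluster belongs to a locus's introns when its midpoint lies in one
#' (`rule = "midpoint"`, default; boundary-straddling clusters are not
#' split), or when its span is fully contained (`rule = "within"`).
#'
#' @param clusters Cluster tibble (passed through [cage_activity()] if the
#'   `midpoint` column is absent).
#' @param introns Intron tibble from [locus_introns()].
#' @param rule Assignment rule.
#' @return The intronic subset of `clusters` with a `locus_id` column.
#' @export
intronic_clusters <- function(clusters, introns, rule = c("midpoint", "within")) {
  rule <- match.arg(rule)
  if (!"midpoint" %in% names(clusters)) clusters <- cage_activity(clusters)
  if (rule == "midpoint") {
    hits <- point_in_rows(tibble(chrom = clusters$chrom, pos = clusters$midpoint),
                          introns)
  } else {
    hits <- overlap_rows(clusters, introns)
    within <- clusters$start[hits$qrow] >= introns$start[hits$srow] &
      clusters$end[hits$qrow] <= introns$end[hits$srow]
    hits <- hits[within, , drop = FALSE]
  }
  hits <- dplyr::distinct(tibble(qrow = hits$qrow,
                                 locus_id = introns$locus_id[hits$srow]))
  out <- clusters[hits$qrow, , drop = FALSE]
  out$locus_id <- hits$locus_id
  out
}

#' Intronic CAGE expression level per locus
#'
#' Sum of CAGE tags over a locus's intronic clusters divided by the total
#' intronic bp of the locus (`denominator = "intron"`, default) or by the
#' locus length (`denominator = "locus"`). Loci without introns get `NA`;
#' loci with introns but no clusters get 0.
#'
#' @param clusters CAGE cluster tibble.
#' @param loci Locus tibble.
#' @param denominator Length used in the denominator.
#' @param rule Cluster-to-intron assignment rule (see [intronic_clusters()]).
#' @return A tibble `locus_id`, `n_clusters`, `total_tags`, `intron_bp`,
#'   `level`.
#' @export
intronic_cage_level <- function(clusters, loci,
                                denominator = c("intron", "locus"),
                                rule = c("midpoint", "within")) {
  denominator <- match.arg(denominator)
  introns <- locus_introns(loci)
  ic <- intronic_clusters(clusters, introns, rule = rule)
  per <- ic |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     total_tags = sum(.data$tag_count), .groups = "drop")
  ibp <- introns |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(intron_bp = sum(.data$end - .data$start), .groups = "drop")
  out <- tibble(locus_id = loci$locus_id,
                locus_bp = loci$end - loci$start) |>
    dplyr::left_join(ibp, by = "locus_id") |>
    dplyr::left_join(per, by = "locus_id") |>
    dplyr::mutate(
      intron_bp = dplyr::coalesce(.data$intron_bp, 0),
      n_clusters = dplyr::coalesce(.data$n_clusters, 0L),
      total_tags = dplyr::coalesce(.data$total_tags, 0),
      level = dplyr::if_else(
        .data$intron_bp > 0,
        .data$total_tags /
          (if (denominator == "intron") .data$intron_bp else .data$locus_bp),
        NA_real_
      )
    ) |>
    dplyr::select("locus_id", "n_clusters", "total_tags", "intron_bp", "level")
  out
}

#' Partition introns into initiation and silent sites
#'
#' Initiation sites are the intersection of the introns with the union of
#' CAGE cluster spans; silent sites are the remainder. The two classes tile
#' the introns exactly.
#'
#' @param introns Intron tibble from [locus_introns()].
#' @param clusters CAGE cluster tibble.
#' @return A tibble of intervals `locus_id`, `chrom`, `start`, `end`,
#'   `class` (`"initiation"` or `"silent"`).
#' @export
partition_introns <- function(introns, clusters) {
  check_intervals(introns, "intron table")
  empty <- tibble(locus_id = character(), chrom = character(),
                  start = integer(), end = integer(), class = character())
  if (nrow(introns) == 0) return(empty)
  cl <- if (nrow(clusters) > 0) {
    reduce_intervals(clusters[, c("chrom", "start", "end")])
  } else {
    empty_intervals()
  }
  hits <- overlap_rows(introns, cl)
  # initiation pieces: clipped intersections (cl is reduced, so pieces within
  # one intron are disjoint)
  ini <- tibble(
    row = hits$qrow,
    start = pmax(introns$start[hits$qrow], cl$start[hits$srow]),
    end = pmin(introns$end[hits$qrow], cl$end[hits$srow])
  ) |> dplyr::arrange(.data$row, .data$start)
  # silent pieces: complement of the pieces within each intron
  sil_hit <- ini |>
    dplyr::group_by(.data$row) |>
    dplyr::reframe({
      piece_s <- start
      piece_e <- end
      bounds <- c(introns$start[row[1]], introns$end[row[1]])
      tibble(start = c(bounds[1], piece_e), end = c(piece_s, bounds[2]))
    }) |>
    dplyr::filter(.data$end > .data$start)
  no_hit <- setdiff(seq_len(nrow(introns)), unique(hits$qrow))
  sil <- dplyr::bind_rows(
    sil_hit,
    tibble(row = no_hit, start = introns$start[no_hit],
           end = introns$end[no_hit])
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(ini, class = "initiation"),
    dplyr::mutate(sil, class = "silent")
  )
  out <- tibble(
    locus_id = introns$locus_id[out$row],
    chrom = introns$chrom[out$row],
    start = as.integer(out$start), end = as.integer(out$end),
    class = out$class
  )
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$locus_id, .data$start, .data$class)
}

#' Summarise an intron partition
#'
#' @param partition Output of [partition_introns()].
#' @return Per-locus tibble `locus_id`, `initiation_bp`, `silent_bp`,
#'   `intron_bp`, `fraction_initiation`.
#' @export
partition_summary <- function(partition) {
  partition |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      initiation_bp = sum((.data$end - .data$start)[.data$class == "initiation"]),
      silent_bp = sum((.data$end - .data$start)[.data$class == "silent"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      intron_bp = .data$initiation_bp + .data$silent_bp,
      fraction_initiation = .data$initiation_bp / .data$intron_bp
    )
}
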