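# Locus construction: merge overlapping transcript models into distinct gene
# loci, then derive the anatomical regions (TSS/TTS flanks, gene body,
# introns) and the intergenic complement.

#' Merge overlapping transcripts into distinct gene loci
#'
#' Transcripts whose spans share at least one bp (on the same chromosome and,
#' when `strand_aware`, the same strand) are merged transitively into a single
#' locus running from the start of the 5'-most exon to the end of the 3'-most
#' exon. The locus exon union is the merged set of member exons.
#'
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param strand_aware Merge within strands only (default). With `FALSE`,
#'   overlapping transcripts on opposite strands collapse into one unstranded
#'   locus.
#' @return A tibble of loci sorted by coordinate: `locus_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_members`, `members` (list of transcript
#'   ids), `exon_starts`, `exon_ends` (list-columns with the exon union).
#' @export
merge_transcripts <- function(transcripts, strand_aware = TRUE) {
  validate_transcripts(transcripts)
  if (nrow(transcripts) == 0) {
    return(tibble(locus_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_members = integer(), members = list(),
                  exon_starts = list(), exon_ends = list()))
  }
  tx <- transcripts
  key <- if (strand_aware) paste0(tx$chrom, "\r", tx$strand) else tx$chrom
  groups <- split(seq_len(nrow(tx)), key)
  loci <- purrr::map(groups, function(idx) {
    ir <- as_iranges0(tx$start[idx], tx$end[idx])
    # min.gapwidth = 0: abutting spans share no bp and must stay separate
    r <- IRanges::reduce(ir, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, r))
    lv <- seq_along(r)
    fac <- factor(comp, levels = lv)
    ex_ir <- as_iranges0(unlist(tx$exon_starts[idx]), unlist(tx$exon_ends[idx]))
    ex_fac <- factor(rep.int(comp, lengths(tx$exon_starts[idx])), levels = lv)
    exl <- IRanges::reduce(S4Vectors::split(ex_ir, ex_fac))
    strands <- vapply(split(tx$strand[idx], fac), function(s) {
      u <- unique(s)
      if (length(u) == 1) u else "*"
    }, character(1))
    tibble(
      chrom = tx$chrom[idx[1]],
      start = IRanges::start(r) - 1L,
      end = IRanges::end(r),
      strand = unname(strands),
      n_members = tabulate(comp, nbins = length(r)),
      members = unname(split(tx$name[idx], fac)),
      exon_starts = unname(as.list(IRanges::start(exl) - 1L)),
      exon_ends = unname(as.list(IRanges::end(exl)))
    )
  }) |> dplyr::bind_rows()
  loci <- dplyr::arrange(loci, .data$chrom, .data$start, .data$end, .data$strand)
  loci$locus_id <- sprintf("locus_%05d", seq_len(nrow(loci)))
  loci[, c("locus_id", "chrom", "start", "end", "strand", "n_members",
           "members", "exon_starts", "exon_ends")]
}

# Orientation-relative interval around an anchor position: covers offsets
# [-up, +down) in the direction of transcription, returned in genomic
# coordinates (strand "*" treated as "+").
oriented_window <- function(anchor, strand, up, down) {
  minus <- strand == "-"
  start <- ifelse(minus, anchor - down + 1, anchor - up)
  end <- ifelse(minus, anchor + up + 1, anchor + down)
  list(start = start, end = end)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive anatomical regions for each gene locus
#'
#' The TSS is the 5' end of the locus in transcription orientation and the
#' TTS the 3' end (single 0-based positions). The gene body runs from
#' `body_trim` bp downstream of the TSS to `body_trim` bp upstream of the
#' TTS and is empty for loci of length <= `2 * body_trim`. Flank windows are
#' oriented in the transcription direction and clipped at chromosome bounds
#' when `chrom_sizes` is supplied. The promoter-proximal window
#' (`promoter_start`/`promoter_end`) spans `tss_up` bp upstream of the TSS to
#' the point where the gene body begins; the TTS-proximal window mirrors it.
#'
#' @param loci Locus tibble from [merge_transcripts()].
#' @param chrom_sizes Optional tibble (`chrom`, `size`) used to clip windows.
#' @param body_trim Distance (bp) trimmed off each end of the locus to form
#'   the gene body.
#' @param tss_up,tss_down Flank extent (bp) upstream/downstream of the TSS.
#' @param tts_up,tts_down Flank extent (bp) upstream/downstream of the TTS.
#' @return One row per locus: `locus_id`, `chrom`, `strand`, `length`,
#'   `tss`, `tts`, `body_start`, `body_end` (NA when the body is empty),
#'   `tss_flank_start/end`, `tts_flank_start/end`, `promoter_start/end`,
#'   `tts_region_start/end`.
#' @export
derive_regions <- function(loci, chrom_sizes = NULL, body_trim = 1000,
                           tss_up = 3000, tss_down = 5000,
                           tts_up = 5000, tts_down = 3000) {
  check_intervals(loci, "locus table")
  minus <- loci$strand == "-"
  tss <- ifelse(minus, loci$end - 1L, loci$start)
  tts <- ifelse(minus, loci$start, loci$end - 1L)
  len <- loci$end - loci$start
  has_body <- len > 2 * body_trim
  body_start <- ifelse(has_body, loci$start + body_trim, NA_integer_)
  body_end <- ifelse(has_body, loci$end - body_trim, NA_integer_)
  tssf <- oriented_window(tss, loci$strand, tss_up, tss_down)
  ttsf <- oriented_window(tts, loci$strand, tts_up, tts_down)
  prom <- oriented_window(tss, loci$strand, tss_up, body_trim)
  ttsr <- oriented_window(tts, loci$strand, body_trim, tts_down)
  out <- tibble(
    locus_id = loci$locus_id, chrom = loci$chrom, strand = loci$strand,
    length = len, tss = as.integer(tss), tts = as.integer(tts),
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    tss_flank_start = tssf$start, tss_flank_end = tssf$end,
    tts_flank_start = ttsf$start, tts_flank_end = ttsf$end,
    promoter_start = prom$start, promoter_end = prom$end,
    tts_region_start = ttsr$start, tts_region_end = ttsr$end
  )
  lo <- 0
  hi <- Inf
  if (!is.null(chrom_sizes)) {
    hi <- chrom_sizes$size[match(out$chrom, chrom_sizes$chrom)]
    if (anyNA(hi)) abort("chrom_sizes does not cover all locus chromosomes")
  }
  for (pre in c("tss_flank", "tts_flank", "promoter", "tts_region")) {
    s <- paste0(pre, "_start")
    e <- paste0(pre, "_end")
    out[[s]] <- as.integer(clip01(out[[s]], lo, hi))
    out[[e]] <- as.integer(clip01(out[[e]], lo, hi))
  }
  out
}

#' Intron intervals of gene loci
#'
#' Introns are the locus span minus the exon union.
#'
#' @param loci Locus tibble from [merge_transcripts()].
#' @return A long tibble `locus_id`, `chrom`, `start`, `end` (possibly zero
#'   rows per locus for single-exon genes).
#' @export
locus_introns <- function(loci) {
  introns_of(loci$locus_id, loci$chrom, loci$start, loci$end,
             loci$exon_starts, loci$exon_ends, id_col = "locus_id")
}

# Vectorised span-minus-exon-union using gaps() on an IRangesList.
introns_of <- function(ids, chrom, start, end, exon_starts, exon_ends,
                       id_col = "locus_id") {
  if (length(ids) == 0) {
    out <- tibble(id = character(), chrom = character(),
                  start = integer(), end = integer())
    names(out)[1] <- id_col
    return(out)
  }
  ir <- as_iranges0(unlist(exon_starts), unlist(exon_ends))
  fac <- factor(rep.int(seq_along(ids), lengths(exon_starts)),
                levels = seq_along(ids))
  irl <- S4Vectors::split(ir, fac)
  g <- IRanges::gaps(irl, start = start + 1L, end = end)
  k <- S4Vectors::elementNROWS(g)
  u <- unlist(g, use.names = FALSE)
  out <- tibble(
    id = rep.int(ids, k), chrom = rep.int(chrom, k),
    start = IRanges::start(u) - 1L, end = IRanges::end(u)
  )
  names(out)[1] <- id_col
  out
}

#' Intergenic complement of the gene loci
#'
#' The unstranded complement of the union of locus spans within
#' `[0, chrom_size)` for every chromosome in `chrom_sizes`.
#'
#' @param loci Locus tibble.
#' @param chrom_sizes Tibble with `chrom`, `size`; must cover every
#'   chromosome carrying a locus.
#' @return A tibble of intergenic intervals `chrom`, `start`, `end`.
#' @export
intergenic_complement <- function(loci, chrom_sizes) {
  check_intervals(loci, "locus table")
  sz <- chrom_sizes$size[match(loci$chrom, chrom_sizes$chrom)]
  if (anyNA(sz)) abort("chrom_sizes does not cover all locus chromosomes")
  if (nrow(loci) > 0 && any(loci$end > sz)) {
    abort("locus extends beyond chromosome size")
  }
  genome <- tibble(chrom = chrom_sizes$chrom, start = 0L,
                   end = as.integer(chrom_sizes$size))
  setdiff_intervals(genome, loci)
}
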