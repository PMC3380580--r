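# Readers and writers for the plain-text formats the pipeline consumes:
# BED/BED12 (via rtracklayer), bedGraph-like methylation TSV, expression TSV,
# chromosome sizes TSV. All readers return tibbles in 0-based half-open
# coordinates; '#' comment lines (e.g. the simulator's seed header) are
# tolerated everywhere.

import_bed_tbl <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) tbl$name <- as.character(mc$name)
  if ("score" %in% names(mc)) tbl$score <- as.numeric(mc$score)
  strand <- as.character(GenomicRanges::strand(gr))
  tbl$strand <- ifelse(strand == "*", "*", strand)
  list(tbl = tbl, gr = gr)
}

#' Read transcript models from a BED12 file
#'
#' Each BED12 line becomes one transcript with its exon blocks resolved to
#' absolute 0-based half-open genomic intervals, stored in the `exon_starts`
#' and `exon_ends` list-columns.
#'
#' @param path Path to a BED12 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `exon_starts`, `exon_ends`.
#' @export
read_transcripts <- function(path) {
  parsed <- import_bed_tbl(path)
  tbl <- parsed$tbl
  gr <- parsed$gr
  mc <- S4Vectors::mcols(gr)
  if (!"blocks" %in% names(mc)) {
    # BED6 or narrower: treat the whole span as a single exon
    tbl$exon_starts <- purrr::map(tbl$start, identity)
    tbl$exon_ends <- purrr::map(tbl$end, identity)
  } else {
    blocks <- mc$blocks
    tbl$exon_starts <- purrr::map2(
      as.list(IRanges::start(blocks)), tbl$start,
      function(rel, s) as.integer(s + rel - 1L)
    )
    tbl$exon_ends <- purrr::map2(
      as.list(IRanges::end(blocks)), tbl$start,
      function(rel, s) as.integer(s + rel)
    )
  }
  if (!"name" %in% names(tbl)) tbl$name <- paste0("tx", seq_len(nrow(tbl)))
  if (!"score" %in% names(tbl)) tbl$score <- 0
  tbl <- tbl[, c("chrom", "start", "end", "name", "score", "strand",
                 "exon_starts", "exon_ends")]
  validate_transcripts(tbl)
}

validate_transcripts <- function(tx) {
  check_intervals(tx, "transcript table")
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]
    ee <- tx$exon_ends[[i]]
    ok <- length(es) == length(ee) && length(es) >= 1 &&
      all(es < ee) &&
      !is.unsorted(es, strictly = TRUE) &&
      all(ee[-length(ee)] <= es[-1]) &&
      es[1] == tx$start[i] && ee[length(ee)] == tx$end[i] &&
      all(es >= tx$start[i]) && all(ee <= tx$end[i])
    if (!ok) {
      abort(paste0("transcript '", tx$name[i], "' (line ", i,
                   "): exon blocks inconsistent with span"))
    }
  }
  tx
}

#' Write transcript models to a BED12 file
#'
#' @param tx A transcript tibble as returned by [read_transcripts()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tx, path, header = NULL) {
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    es <- tx$exon_starts[[i]]
    ee <- tx$exon_ends[[i]]
    paste(
      tx$chrom[i], tx$start[i], tx$end[i], tx$name[i],
      tx$score[i], tx$strand[i], tx$start[i], tx$end[i], "0",
      length(es),
      paste0(paste(ee - es, collapse = ","), ","),
      paste0(paste(es - tx$start[i], collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(c(if (!is.null(header)) paste0("# ", header), lines), path)
  invisible(path)
}

#' Write intervals to a BED6 file
#'
#' @param df A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path, header = NULL) {
  name <- df$name %||% rep(".", nrow(df))
  score <- df$score %||% rep(0, nrow(df))
  strand <- df$strand %||% rep(".", nrow(df))
  lines <- paste(df$chrom, df$start, df$end, name, score, strand, sep = "\t")
  writeLines(c(if (!is.null(header)) paste0("# ", header), lines), path)
  invisible(path)
}

#' Read mapped tag intervals or CAGE clusters from a BED file
#'
#' For CAGE clusters the BED score column carries the tag count.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A tibble with `chrom`, `start`, `end`, and when present `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  import_bed_tbl(path)$tbl
}

#' Read per-CpG percent methylation records
#'
#' Expects a bedGraph-like TSV with five columns: chrom, start, end, percent
#' methylation (0-100) and read coverage.
#'
#' @param path Path to the methylation TSV.
#' @return A tibble with columns `chrom`, `start`, `end`, `percent`,
#'   `coverage`.
#' @export
read_methylation <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "percent", "coverage"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      percent = readr::col_double(),
      coverage = readr::col_integer()
    ),
    comment = "#", progress = FALSE
  )
  if (nrow(df) > 0 && any(df$percent < 0 | df$percent > 100)) {
    abort("methylation percent outside [0, 100]")
  }
  df
}

#' Write per-CpG methylation records
#' @param cpgs Methylation tibble (see [read_methylation()]).
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(cpgs, path, header = NULL) {
  write_tsv_with_header(
    cpgs[, c("chrom", "start", "end", "percent", "coverage")], path, header)
}

write_tsv_with_header <- function(df, path, header = NULL,
                                  col_names = FALSE) {
  writeLines(if (is.null(header)) character() else paste0("# ", header), path)
  readr::write_tsv(df, path, col_names = col_names, append = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Two-column TSV: gene/transcript identifier and log2 signal.
#'
#' @param path Path to the expression TSV.
#' @return A tibble with columns `id`, `log2_expr`.
#' @export
read_expression <- function(path) {
  readr::read_tsv(
    path, col_names = c("id", "log2_expr"),
    col_types = readr::cols(id = readr::col_character(),
                            log2_expr = readr::col_double()),
    comment = "#", progress = FALSE
  )
}

#' Write a per-gene expression table
#' @param expr Expression tibble (`id`, `log2_expr`).
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, header = NULL) {
  write_tsv_with_header(expr[, c("id", "log2_expr")], path, header)
}

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a TSV with chromosome name and length in bp.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(
    path, col_names = c("chrom", "size"),
    col_types = readr::cols(chrom = readr::col_character(),
                            size = readr::col_double()),
    comment = "#", progress = FALSE
  )
}

#' Write a chromosome sizes table
#' @param sizes Tibble with `chrom`, `size`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path, header = NULL) {
  write_tsv_with_header(sizes[, c("chrom", "size")], path, header)
}
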