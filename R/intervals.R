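# Internal interval arithmetic, backed by IRanges. Tables are tibbles with at
# least chrom/start/end; coordinates 0-based half-open.

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

check_intervals <- function(df, what = "interval table") {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame"))
  miss <- setdiff(c("chrom", "start", "end"), names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) > 0) {
    bad <- which(!(df$start >= 0 & df$end > df$start))
    if (length(bad) > 0) {
      abort(paste0(what, ": invalid interval at row ", bad[1],
                   " (need 0 <= start < end)"))
    }
  }
  invisible(df)
}

empty_intervals <- function(extra = character()) {
  out <- tibble(chrom = character(), start = integer(), end = integer())
  for (nm in extra) out[[nm]] <- character()
  out
}

# Overlap join between two interval tables; returns row-index pairs.
overlap_rows <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(qrow = integer(), srow = integer()))
  }
  qs <- split(seq_len(nrow(query)), query$chrom)
  ss <- split(seq_len(nrow(subject)), subject$chrom)
  chroms <- intersect(names(qs), names(ss))
  out <- lapply(chroms, function(ch) {
    qi <- qs[[ch]]
    si <- ss[[ch]]
    hits <- IRanges::findOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si])
    )
    tibble(
      qrow = qi[S4Vectors::queryHits(hits)],
      srow = si[S4Vectors::subjectHits(hits)]
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$qrow, .data$srow)
}

# Point-in-interval join: position column `pos` (single bp) against intervals.
point_in_rows <- function(pos_df, subject) {
  q <- tibble(chrom = pos_df$chrom, start = pos_df$pos, end = pos_df$pos + 1L)
  overlap_rows(q, subject)
}

# Merge overlapping/adjacent-free union per chromosome (and optionally strand).
reduce_intervals <- function(df, by_strand = FALSE) {
  check_intervals(df)
  if (nrow(df) == 0) return(empty_intervals())
  keys <- c("chrom", if (by_strand && "strand" %in% names(df)) "strand")
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe({
      r <- IRanges::reduce(as_iranges0(.data$start, .data$end))
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Set difference a \ b per chromosome (strand ignored).
setdiff_intervals <- function(a, b) {
  check_intervals(a)
  check_intervals(b)
  if (nrow(a) == 0) return(empty_intervals())
  bs <- split(seq_len(nrow(b)), b$chrom)
  a |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe({
      ch <- .data$chrom[1]
      ia <- as_iranges0(.data$start, .data$end)
      bi <- bs[[ch]]
      ib <- if (is.null(bi)) IRanges::IRanges() else as_iranges0(b$start[bi], b$end[bi])
      r <- IRanges::setdiff(ia, ib)
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Intersection a  b per chromosome (strand ignored).
intersect_intervals <- function(a, b) {
  check_intervals(a)
  check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  bs <- split(seq_len(nrow(b)), b$chrom)
  a |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe({
      ch <- .data$chrom[1]
      bi <- bs[[ch]]
      if (is.null(bi)) {
        tibble(start = integer(), end = integer())
      } else {
        r <- IRanges::intersect(
          as_iranges0(.data$start, .data$end),
          as_iranges0(b$start[bi], b$end[bi])
        )
        tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
      }
    }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

total_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(as.numeric(df$end) - as.numeric(df$start))
}
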