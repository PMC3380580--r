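# Quantile binning of genes, per-bin aggregation and Pearson regression on
# bin means -- the statistical engine relating methylation, expression and
# chromatin measures.

#' Assign genes to ranked equal-count bins
#'
#' Rows are sorted ascending by `value` (ties broken stably by the `id`
#' column so that permuting the input never changes the assignment) and split
#' into `k` contiguous groups whose sizes differ by at most one; remainder
#' rows go to the lowest bins. Bin 1 holds the lowest values.
#'
#' @param df A data frame with one row per gene.
#' @param value Column to rank by (tidy-eval).
#' @param k Number of bins (>= 2).
#' @param id Identifier column used as tie-break (tidy-eval); defaults to
#'   `locus_id` when present, otherwise the first column.
#' @return `df` with an integer `bin` column.
#' @export
quantile_bins <- function(df, value, k, id = NULL) {
  if (k < 2) abort("k must be >= 2")
  n <- nrow(df)
  if (n < k) abort(paste0("need at least k = ", k, " rows, got ", n))
  v <- dplyr::pull(df, {{ value }})
  if (any(!is.finite(v))) abort("ranking values must be finite")
  id_quo <- rlang::enquo(id)
  ids <- if (rlang::quo_is_null(id_quo)) {
    if ("locus_id" %in% names(df)) df$locus_id else df[[1]]
  } else {
    dplyr::pull(df, {{ id }})
  }
  ord <- order(v, ids, method = "radix")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  assignment <- integer(n)
  assignment[ord] <- rep.int(seq_len(k), sizes)
  dplyr::mutate(df, bin = assignment)
}

#' Aggregate per-bin means
#'
#' @param df A data frame with a `bin` column (see [quantile_bins()]).
#' @param x,y Columns to average per bin (tidy-eval); `y` may contain `NA`,
#'   which are dropped from `mean_y` (`n_y` counts the non-missing members).
#' @return A `BinSummary` tibble: `bin`, `n`, `n_y`, `mean_x`, `mean_y`.
#' @export
bin_aggregate <- function(df, x, y) {
  if (!"bin" %in% names(df)) abort("df must have a bin column")
  df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_y = sum(!is.na({{ y }})),
      mean_x = mean({{ x }}),
      mean_y = if (all(is.na({{ y }}))) NA_real_
               else mean({{ y }}, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin)
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation computed by the direct covariance formula, with
#' the two-sided p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (pairs with `NA` in either are dropped).
#' @return A tibble `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("pearson_cor needs at least 3 complete pairs")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("undefined correlation: constant input")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Binned Pearson regression
#'
#' Genes are grouped into `k` ranked equal-count bins of `x`
#' ([quantile_bins()]), per-bin means of `x` and `y` are formed
#' ([bin_aggregate()]), and the Pearson correlation is computed over the
#' usable (non-missing) bin-mean pairs. The raw per-gene correlation is also
#' reported for transparency.
#'
#' @param df Data frame with one row per gene.
#' @param x,y Columns (tidy-eval): ranking/abscissa variable and response.
#' @param k Number of bins (>= 3).
#' @param id Tie-break identifier column (see [quantile_bins()]).
#' @return An object of class `gb_binreg` with elements `bins` (the
#'   `BinSummary` tibble), `binned` and `raw` correlation tibbles,
#'   `peak_bin` (bin index with the highest `mean_y`), `k`, and `vars`.
#' @export
bin_regress <- function(df, x, y, k = 100, id = NULL) {
  if (k < 3) abort("k must be >= 3 (two bins always give |r| = 1)")
  binned <- quantile_bins(df, {{ x }}, k = k, id = {{ id }})
  bins <- bin_aggregate(binned, {{ x }}, {{ y }})
  usable <- bins[!is.na(bins$mean_y), , drop = FALSE]
  if (nrow(usable) < 3) abort("fewer than 3 usable bins")
  cor_binned <- pearson_cor(usable$mean_x, usable$mean_y)
  xs <- dplyr::pull(df, {{ x }})
  ys <- dplyr::pull(df, {{ y }})
  cor_raw <- tryCatch(pearson_cor(xs, ys), error = function(e) {
    tibble(r = NA_real_, p = NA_real_, n = sum(!is.na(xs) & !is.na(ys)))
  })
  structure(
    list(
      bins = bins,
      binned = cor_binned,
      raw = cor_raw,
      peak_bin = usable$bin[which.max(usable$mean_y)],
      k = k,
      vars = c(x = sub("^\\.data\\$", "", rlang::as_label(rlang::enquo(x))),
               y = sub("^\\.data\\$", "", rlang::as_label(rlang::enquo(y))))
    ),
    class = "gb_binreg"
  )
}

#' @export
print.gb_binreg <- function(x, ...) {
  cat(sprintf(
    "Binned Pearson regression of %s on %s (%d bins, %d usable)\n",
    x$vars["y"], x$vars["x"], x$k, x$binned$n
  ))
  cat(sprintf("  bin means: r = %.4f, p = %.3g; raw: r = %.4f\n",
              x$binned$r, x$binned$p, x$raw$r))
  cat(sprintf("  peak bin (highest mean %s): %d\n", x$vars["y"], x$peak_bin))
  invisible(x)
}

#' @describeIn bin_regress Per-bin means as a tibble.
#' @param x A `gb_binreg` object.
#' @param ... Unused.
#' @export
tidy.gb_binreg <- function(x, ...) x$bins

#' @describeIn bin_regress One-row model summary: `r`, `p`, `n_bins` for the
#'   bin-mean correlation, `r_raw`, `p_raw`, `n_genes` for the per-gene
#'   correlation, `peak_bin`, `k`.
#' @export
glance.gb_binreg <- function(x, ...) {
  tibble(
    r = x$binned$r, p = x$binned$p, n_bins = x$binned$n,
    r_raw = x$raw$r, p_raw = x$raw$p, n_genes = x$raw$n,
    peak_bin = x$peak_bin, k = x$k
  )
}

#' Length-stratified binned regression
#'
#' Repeats [bin_regress()] within the shortest and longest `fraction` of
#' genes, to check that a relationship is not an artefact of gene length.
#' The per-stratum bin count is `max(10, floor(n_stratum / 20))`.
#'
#' @param df Data frame with one row per gene.
#' @param length Gene length column (tidy-eval).
#' @param x,y Regression columns (tidy-eval).
#' @param fraction Fraction of genes in each stratum (default 0.2).
#' @param id Tie-break identifier column.
#' @return A list with `gb_binreg` elements `short` and `long` and the
#'   stratum size `n_stratum`.
#' @export
length_stratified <- function(df, length, x, y, fraction = 0.2, id = NULL) {
  n <- nrow(df)
  n_s <- floor(n * fraction)
  if (n_s < 10) abort("length stratum too small (need >= 10 genes)")
  lens <- dplyr::pull(df, {{ length }})
  id_quo <- rlang::enquo(id)
  ids <- if (rlang::quo_is_null(id_quo)) {
    if ("locus_id" %in% names(df)) df$locus_id else df[[1]]
  } else {
    dplyr::pull(df, {{ id }})
  }
  ord <- order(lens, ids, method = "radix")
  k <- max(10, n_s %/% 20)
  list(
    short = bin_regress(df[ord[seq_len(n_s)], ], {{ x }}, {{ y }},
                        k = k, id = {{ id }}),
    long = bin_regress(df[ord[seq.int(n - n_s + 1, n)], ], {{ x }}, {{ y }},
                       k = k, id = {{ id }}),
    n_stratum = n_s
  )
}
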