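# ggplot2 layer over the result objects. Plots are a thin optional view;
# all analyses assert on the tables.

#' @describeIn metagene_profile Plot the profile: one line per expression
#'   bin, faceted by anchor (TSS/TTS), x in bp relative to the anchor in
#'   transcription orientation.
#' @param object A `gb_metagene` object.
#' @param ... Unused.
#' @export
autoplot.gb_metagene <- function(object, ...) {
  df <- object$profile
  df$anchor <- factor(df$anchor, levels = c("TSS", "TTS"))
  ggplot2::ggplot(
    df[!is.na(df$mean_percent), ],
    ggplot2::aes(x = .data$offset + object$window / 2, y = .data$mean_percent,
                 colour = factor(.data$bin))
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$anchor), scales = "free_x") +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "mean methylation (%)", colour = "expression bin") +
    ggplot2::theme_minimal()
}

#' @describeIn bin_regress Plot bin means with the Pearson r/p annotation.
#' @param object A `gb_binreg` object.
#' @export
autoplot.gb_binreg <- function(object, ...) {
  df <- object$bins[!is.na(object$bins$mean_y), ]
  lab <- sprintf("r = %.3f, P = %.2g", object$binned$r, object$binned$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_x, y = .data$mean_y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = paste("bin mean", object$vars["x"]),
                  y = paste("bin mean", object$vars["y"])) +
    ggplot2::theme_minimal()
}

#' Bar plot of genic versus intergenic methylation
#'
#' @param gi Output of [genic_vs_intergenic()].
#' @return A ggplot object.
#' @export
plot_genic_intergenic <- function(gi) {
  ggplot2::ggplot(gi, ggplot2::aes(x = .data$class, y = .data$mean_percent)) +
    ggplot2::geom_col(width = 0.6, fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent - .data$se,
                   ymax = .data$mean_percent + .data$se), width = 0.15) +
    ggplot2::labs(x = NULL, y = "mean methylation (%)") +
    ggplot2::theme_minimal()
}

#' Joint methylation / intronic-expression curves across expression bins
#'
#' Plots bin-mean gene-body methylation and intronic CAGE level (rescaled to
#' the methylation axis) against bin-mean expression, the joint view of the
#' two relationships around their common inflection.
#'
#' @param joint The `joint` table of a [run_all()] result.
#' @return A ggplot object.
#' @export
plot_joint_curves <- function(joint) {
  df <- joint[!is.na(joint$mean_body_meth) & !is.na(joint$mean_intronic_cage), ]
  scale <- max(df$mean_body_meth, na.rm = TRUE) /
    max(df$mean_intronic_cage[df$mean_intronic_cage > 0], na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_log2_expr)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_body_meth,
                                    colour = "gene-body methylation (%)")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_intronic_cage * scale,
                                    colour = "intronic CAGE (scaled)")) +
    ggplot2::labs(x = "bin mean log2 expression", y = "level", colour = NULL) +
    ggplot2::theme_minimal()
}
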