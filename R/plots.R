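# Figures mirror the standard codon-usage-bias panel set; every plot has a
# TSV twin written by write_genome_results().

save_plot_quiet <- function(p, path, width = 6, height = 5) {
  suppressMessages(ggplot2::ggsave(path, plot = p, width = width,
                                   height = height))
  invisible(path)
}

#' ENC versus GC3s plot with the mutation-only expectation curve
#'
#' @param diagnostics Data frame from [selection_diagnostics()].
#' @param curve_step Sampling step for the expectation curve.
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(diagnostics, curve_step = 0.001) {
  s <- seq(0, 1, by = curve_step)
  curve_df <- data.frame(gc3s = s, enc = enc_expected(s))
  ok <- diagnostics[is.finite(diagnostics$enc_obs), , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = gc3s, y = enc_obs)) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = gc3s, y = enc),
                       linewidth = 0.4, colour = "black") +
    ggplot2::geom_point(alpha = 0.7, size = 1.4, colour = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(15, 62)) +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::theme_classic()
}

#' PR2 bias plot
#'
#' @param diagnostics Data frame from [selection_diagnostics()]; genes
#'   with undefined PR2 coordinates are dropped.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(diagnostics) {
  ok <- diagnostics[diagnostics$pr2_defined, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = pr2_x, y = pr2_y)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4, colour = "#b2182b") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)") +
    ggplot2::theme_classic()
}

#' Neutrality plot (GC12 versus GC3) with its regression line
#'
#' @param gene_comp Data frame from [gene_composition()].
#' @param fit A [neutrality_fit()] result for the same genes.
#' @return A ggplot object.
#' @export
plot_neutrality <- function(gene_comp, fit) {
  if (fit$orientation == "gc12_x") {
    df <- data.frame(x = gene_comp$gc12, y = gene_comp$gc3)
    labs <- c("GC12", "GC3")
  } else {
    df <- data.frame(x = gene_comp$gc3, y = gene_comp$gc12)
    labs <- c("GC3", "GC12")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4, colour = "#4d9221") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linewidth = 0.4) +
    ggplot2::labs(x = labs[1L], y = labs[2L],
                  subtitle = sprintf("y = %.3f x + %.3f (r = %.2f)",
                                     fit$slope, fit$intercept, fit$r)) +
    ggplot2::theme_classic()
}

#' ENC-ratio frequency distribution
#'
#' @param hist_df Data frame from [enc_ratio_histogram()].
#' @return A ggplot object.
#' @export
plot_enc_ratio_hist <- function(hist_df) {
  ggplot2::ggplot(hist_df,
                  ggplot2::aes(x = (lower + upper) / 2,
                               y = count)) +
    ggplot2::geom_col(width = (hist_df$upper - hist_df$lower)[1L] * 0.9,
                      fill = "#2166ac") +
    ggplot2::labs(x = "ENC ratio", y = "Number of genes") +
    ggplot2::theme_classic()
}

#' Correspondence-analysis biplot (Axis 1 versus Axis 2)
#'
#' @param ca A [correspondence_analysis()] result with at least 2 axes.
#' @return A ggplot object.
#' @export
plot_ca <- function(ca) {
  stopifnot(inherits(ca, "ca_result"), ca$n_axes >= 2L)
  rows <- data.frame(x = ca$row_scores[, 1L], y = ca$row_scores[, 2L],
                     what = "gene")
  cols <- data.frame(x = ca$col_scores[, 1L], y = ca$col_scores[, 2L],
                     what = "codon")
  df <- rbind(rows, cols)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = what)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_point(alpha = 0.7, size = 1.3) +
    ggplot2::scale_colour_manual(values = c(gene = "#2166ac",
                                            codon = "#b2182b")) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", ca$inertia_pct[1L]),
                  y = sprintf("Axis 2 (%.1f%%)", ca$inertia_pct[2L]),
                  colour = NULL) +
    ggplot2::theme_classic()
}
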