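#' Expected ENC under mutation pressure alone
#'
#' Wright's standard curve for the ENC-GC3s plot:
#' ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2), with s the synonymous
#' third-position GC content. Genes on the curve are compatible with purely
#' mutational bias; genes below it suggest selection.
#'
#' @param gc3s Numeric vector of GC3s values in \[0, 1\].
#' @return Expected ENC values.
#' @examples
#' enc_expected(c(0, 0.5, 1))  # 31.0, 60.5, 32.0
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0) || any(gc3s > 1)) {
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC ratio: relative shortfall of observed versus expected ENC
#'
#' (ENC_exp - ENC_obs) / ENC_exp. Positive values mean the gene uses fewer
#' effective codons than mutation pressure alone predicts.
#'
#' @param enc_exp Expected ENC (> 0).
#' @param enc_obs Observed ENC.
#' @return Numeric ratio.
#' @export
enc_ratio <- function(enc_exp, enc_obs) {
  if (any(enc_exp <= 0)) stop("enc_exp must be positive", call. = FALSE)
  (enc_exp - enc_obs) / enc_exp
}

#' Frequency distribution of ENC ratios
#'
#' Half-open bins \[a, a + w) with edges aligned to zero, covering the
#' observed range; empty interior bins are reported as zero counts.
#'
#' @param ratios Non-empty numeric vector.
#' @param bin_width Bin width (default 0.05).
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
enc_ratio_histogram <- function(ratios, bin_width = 0.05) {
  if (length(ratios) == 0L) stop("no ratios supplied", call. = FALSE)
  idx <- floor(ratios / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), integer(1))
  data.frame(lower = rng * bin_width, upper = (rng + 1) * bin_width,
             count = counts)
}

#' PR2 plot coordinates for one gene
#'
#' x = G3 / (G3 + C3), y = A3 / (A3 + T3), from third-position base
#' fractions. Unbiased usage sits at (0.5, 0.5). A zero denominator makes
#' the point undefined: NA coordinates with attribute `undefined = TRUE`
#' (flagged, not errored; such genes are excluded from the plot).
#'
#' @param a3,t3,c3,g3 Third-position base fractions.
#' @return Named numeric `c(x, y)`; attribute `undefined`.
#' @export
pr2_point <- function(a3, t3, c3, g3) {
  if ((g3 + c3) <= 0 || (a3 + t3) <= 0) {
    return(structure(c(x = NA_real_, y = NA_real_), undefined = TRUE))
  }
  structure(c(x = g3 / (g3 + c3), y = a3 / (a3 + t3)), undefined = FALSE)
}

#' Per-gene mutation-versus-selection diagnostics
#'
#' Combines for every gene its GC3s, observed ENC, expected ENC from
#' [enc_expected()], the ENC ratio, and the PR2 coordinates (synonymous
#' third-position dialect by default). Genes with undefined ENC carry NA;
#' genes with an undefined PR2 denominator carry NA coordinates and
#' `pr2_defined = FALSE`.
#'
#' @param x A `cds_set` or counts matrix.
#' @param space A [build_codon_space()] object.
#' @param synonymous_only Dialect for the third-position fractions feeding
#'   GC3s and the default PR2.
#' @param pr2_variant `"synonymous"` feeds PR2 with the third-position
#'   fractions over all 59 analysis codons; `"fourfold"` restricts to the
#'   five strictly four-fold degenerate families (the classical PR2
#'   formulation, in which every third base is available to each family so
#'   unbiased usage sits at the centre exactly -- over the full analysis
#'   set the code's purine-ending two-fold families contribute G3 but
#'   never C3, displacing even unbiased genes from (0.5, 0.5)).
#' @return Data frame: `gene_id`, `gc3s`, `enc_obs`, `enc_exp`,
#'   `enc_ratio`, `pr2_x`, `pr2_y`, `pr2_defined`.
#' @export
selection_diagnostics <- function(x, space = build_codon_space(),
                                  synonymous_only = TRUE,
                                  pr2_variant = c("synonymous", "fourfold")) {
  pr2_variant <- match.arg(pr2_variant)
  m <- as_counts_matrix(x)
  e <- enc_per_gene(m, space)
  fourfold_codons <- unlist(space$families[space$deg_classes[["4"]]],
                            use.names = FALSE)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    p3 <- third_position_composition(m[i, ], space,
                                     synonymous_only = synonymous_only)
    s <- unname(p3[["C3"]] + p3[["G3"]])
    p3_pr2 <- if (pr2_variant == "fourfold") {
      cnt4 <- m[i, ][intersect(names(m[i, ]), fourfold_codons)]
      if (sum(cnt4) >= 1) {
        third_position_composition(cnt4, space, synonymous_only = FALSE)
      } else c(A3 = 0, T3 = 0, C3 = 0, G3 = 0)
    } else p3
    pt <- pr2_point(p3_pr2[["A3"]], p3_pr2[["T3"]], p3_pr2[["C3"]],
                    p3_pr2[["G3"]])
    ee <- enc_expected(s)
    data.frame(
      gene_id = rownames(m)[i],
      gc3s = s, enc_obs = unname(e[i]), enc_exp = ee,
      enc_ratio = if (is.na(e[i])) NA_real_ else enc_ratio(ee, e[i]),
      pr2_x = unname(pt[["x"]]), pr2_y = unname(pt[["y"]]),
      pr2_defined = !isTRUE(attr(pt, "undefined")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Neutrality-plot regression (GC12 versus GC3)
#'
#' Ordinary least squares of GC3 on GC12 in the default orientation
#' (`"gc12_x"`: x = GC12, y = GC3); `"gc3_x"` swaps the axes. The slope is
#' read as the mutational share of codon usage bias:
#' `mutation_pct = 100 * slope`, `selection_pct = 100 - mutation_pct`.
#' A slope near 1 indicates mutation-driven bias, near 0
#' selection-dominated bias.
#'
#' @param gc12,gc3 Per-gene GC12 and GC3 fractions (length >= 3).
#' @param genome_id Label.
#' @param orientation Which variable goes on x.
#' @return Object of class `neutrality_fit`: list with `genome_id`,
#'   `slope`, `intercept`, `r` (Pearson), `p_value`, `mutation_pct`,
#'   `selection_pct`, `n`, `orientation`.
#' @export
neutrality_fit <- function(gc12, gc3, genome_id = "genome",
                           orientation = c("gc12_x", "gc3_x")) {
  orientation <- match.arg(orientation)
  ok <- is.finite(gc12) & is.finite(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  if (length(gc12) < 3L) {
    stop("insufficient data: need at least 3 genes", call. = FALSE)
  }
  xv <- if (orientation == "gc12_x") gc12 else gc3
  yv <- if (orientation == "gc12_x") gc3 else gc12
  if (stats::var(xv) <= 0) {
    stop("insufficient data: zero variance on the x variable", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (stats::var(yv) > 0) {
    ct <- stats::cor.test(xv, yv)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- 0; p <- 1
  }
  structure(
    list(genome_id = genome_id, slope = slope, intercept = intercept,
         r = r, p_value = p,
         mutation_pct = 100 * slope, selection_pct = 100 * (1 - slope),
         n = length(xv), orientation = orientation),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> %s: slope %.3f (r = %.3f, p = %.3g, n = %d)\n",
    x$genome_id, x$slope, x$r, x$p_value, x$n))
  cat(sprintf("  mutation %.1f%% / selection %.1f%%\n",
              x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' Neutrality fit as a one-row data frame
#'
#' @param fit A [neutrality_fit()] result.
#' @return One-row data frame.
#' @export
neutrality_row <- function(fit) {
  data.frame(genome_id = fit$genome_id, slope = fit$slope,
             intercept = fit$intercept, r = fit$r, p_value = fit$p_value,
             mutation_pct = fit$mutation_pct,
             selection_pct = fit$selection_pct, n = fit$n,
             orientation = fit$orientation, stringsAsFactors = FALSE)
}
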