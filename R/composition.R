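#' Base composition at third codon positions
#'
#' Fractions of A, T, C, G at the third position of codons. With
#' `synonymous_only = TRUE` (the default, the codonW convention) only the
#' 59 analysis codons contribute: Met (ATG), Trp (TGG), and the stop codons
#' are excluded. With `synonymous_only = FALSE` every counted codon
#' contributes its third base.
#'
#' @param counts Named codon-count vector (any subset of the 64 codons).
#' @param space A [build_codon_space()] object.
#' @param synonymous_only Restrict to the 59-codon analysis set?
#' @return Named numeric `c(A3, T3, C3, G3)` summing to 1.
#' @export
third_position_composition <- function(counts, space = build_codon_space(),
                                       synonymous_only = TRUE) {
  assert_codon_space(space)
  counts <- full_counts(counts)
  if (synonymous_only) counts <- counts[space$analysis_codons]
  total <- sum(counts)
  if (total < 1) {
    stop("undefined statistic: no codons in the included set", call. = FALSE)
  }
  third <- substr(names(counts), 3L, 3L)
  out <- vapply(c("A", "T", "C", "G"),
                function(b) sum(counts[third == b]) / total, numeric(1))
  names(out) <- c("A3", "T3", "C3", "G3")
  out
}

#' Positional GC content
#'
#' G+C fraction at codon position 1, 2, 3, or over all positions, computed
#' over ALL codons of the input (including Met, Trp, and any stop codon) --
#' the EMBOSS cusp convention used for GC/GC1/GC2/GC3 reporting, as opposed
#' to the synonymous-only third-position statistics of
#' [third_position_composition()].
#'
#' @param x Named codon-count vector or a DNA string (character of length
#'   1, length divisible by 3).
#' @param position `1`, `2`, `3`, or `"all"`.
#' @return Fraction in \[0, 1\].
#' @examples
#' positional_gc("ATGGCGTAA", 1)  # 1/3
#' @export
positional_gc <- function(x, position = "all") {
  position <- as.character(position)
  if (!position %in% c("1", "2", "3", "all")) {
    stop("position must be 1, 2, 3 or \"all\"", call. = FALSE)
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    x <- codon_counts(x)
  }
  counts <- full_counts(x)
  total <- sum(counts)
  if (total < 1) stop("undefined statistic: no codons", call. = FALSE)
  gc_at <- function(p) {
    b <- substr(names(counts), p, p)
    sum(counts[b %in% c("G", "C")]) / total
  }
  if (position == "all") {
    mean(c(gc_at(1L), gc_at(2L), gc_at(3L)))
  } else {
    gc_at(as.integer(position))
  }
}

#' Synonymous third-position GC content (GC3s)
#'
#' G+C fraction at the third position of the 59 synonymous analysis codons
#' (Met, Trp, stops excluded).
#'
#' @inheritParams third_position_composition
#' @return Fraction in \[0, 1\].
#' @export
gc3s <- function(counts, space = build_codon_space()) {
  p3 <- third_position_composition(counts, space, synonymous_only = TRUE)
  unname(p3[["C3"]] + p3[["G3"]])
}

#' Full composition summary for one gene or pooled genome
#'
#' Combines the two composition dialects in one row: synonymous-only
#' third-position fractions (A3/T3/C3/G3, GC3s) and all-codon positional GC
#' (GC, GC1, GC2, GC3, with GC12 = (GC1+GC2)/2).
#'
#' @param counts Named codon-count vector.
#' @param space A [build_codon_space()] object.
#' @param scope_id Label for the row (gene or genome id).
#' @param synonymous_only Dialect for the A3/T3/C3/G3 block.
#' @return One-row data frame with columns `scope_id`, `a3`, `t3`, `c3`,
#'   `g3`, `gc_all`, `gc1`, `gc2`, `gc3`, `gc12`, `gc3s` (all fractions).
#' @export
composition_stats <- function(counts, space = build_codon_space(),
                              scope_id = "scope", synonymous_only = TRUE) {
  p3 <- third_position_composition(counts, space, synonymous_only = synonymous_only)
  gc1 <- positional_gc(counts, 1)
  gc2 <- positional_gc(counts, 2)
  data.frame(
    scope_id = scope_id,
    a3 = unname(p3[["A3"]]), t3 = unname(p3[["T3"]]),
    c3 = unname(p3[["C3"]]), g3 = unname(p3[["G3"]]),
    gc_all = positional_gc(counts, "all"),
    gc1 = gc1, gc2 = gc2, gc3 = positional_gc(counts, 3),
    gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s(counts, space),
    stringsAsFactors = FALSE
  )
}

#' Per-gene composition table for a filtered CDS set
#'
#' @param x A `cds_set` (or genes x 64 counts matrix).
#' @inheritParams composition_stats
#' @return Data frame, one row per gene, columns as in
#'   [composition_stats()] with `scope_id` renamed `gene_id`.
#' @export
gene_composition <- function(x, space = build_codon_space(),
                             synonymous_only = TRUE) {
  m <- as_counts_matrix(x)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    composition_stats(m[i, ], space, scope_id = rownames(m)[i],
                      synonymous_only = synonymous_only)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "scope_id"] <- "gene_id"
  out
}

#' Genome-level composition from pooled filtered CDS counts
#'
#' Pools the codon counts of all filtered genes and computes one
#' composition row; this is the Table-1-style per-genome summary (computed
#' from filtered CDSs, not whole-genome sequence).
#'
#' @inheritParams gene_composition
#' @param genome_id Row label.
#' @return One-row data frame.
#' @export
genome_composition <- function(x, space = build_codon_space(),
                               genome_id = NULL, synonymous_only = TRUE) {
  m <- as_counts_matrix(x)
  if (is.null(genome_id)) {
    genome_id <- if (inherits(x, "cds_set")) x$report$genome_id else "genome"
  }
  out <- composition_stats(colSums(m), space, scope_id = genome_id,
                           synonymous_only = synonymous_only)
  names(out)[names(out) == "scope_id"] <- "genome_id"
  out
}

#' Render a composition table with percentages
#'
#' Converts the fractional composition columns to percentages rounded to
#' two decimals, the layout used for per-genome reporting (A3% ... GC3%).
#'
#' @param comp Data frame from [genome_composition()] (possibly several
#'   rows bound together).
#' @return Data frame with percentage columns.
#' @export
composition_percent_table <- function(comp) {
  pct <- function(v) round(100 * v, 2)
  data.frame(
    genome_id = comp[[1L]],
    A3_pct = pct(comp$a3), T3_pct = pct(comp$t3),
    C3_pct = pct(comp$c3), G3_pct = pct(comp$g3),
    GC_pct = pct(comp$gc_all), GC1_pct = pct(comp$gc1),
    GC2_pct = pct(comp$gc2), GC3_pct = pct(comp$gc3),
    stringsAsFactors = FALSE
  )
}
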