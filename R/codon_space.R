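#' Genetic-code bookkeeping for codon usage analysis
#'
#' Builds the codon bookkeeping object used throughout the package: the
#' codon-to-amino-acid map, the synonymous families with their degeneracy,
#' and the 59-codon analysis set obtained by excluding the two single-codon
#' amino acids (Met, Trp) and the three stop codons. Chloroplast CDSs
#' translate identically under the standard code and the bacterial/plastid
#' code (NCBI table 11), so both identifiers resolve to the same table;
#' alternative table-11 start codons are irrelevant here because the CDS
#' filter demands an ATG start.
#'
#' Codons are represented in the DNA alphabet (T, not U); rendering with U
#' is a display concern only.
#'
#' @param code_id Genetic-code identifier. One of `"standard"`, `"plastid"`,
#'   or `"11"` (all equivalent codon-to-amino-acid assignments).
#' @return An object of class `codon_space`: a list with elements
#'   `code_id`, `codon_table` (named character, 64 codons to one-letter
#'   amino acids, `"*"` for stops), `family_of` (same map restricted
#'   semantics used for family lookup), `families` (named list: amino acid
#'   to synonymous codon vector, 18 analysis families), `degeneracy`
#'   (named integer per family), `deg_classes` (families split by
#'   degeneracy class 2/3/4/6), `analysis_codons` (59 codons),
#'   `stop_codons`, and `excluded_single_codons` (ATG, TGG).
#' @examples
#' sp <- build_codon_space()
#' length(sp$analysis_codons)  # 59
#' sp$degeneracy[["L"]]        # 6
#' @export
build_codon_space <- function(code_id = "standard") {
  if (!is.character(code_id) || length(code_id) != 1L ||
      !code_id %in% c("standard", "plastid", "11")) {
    stop("unknown genetic code identifier: ",
         paste(format(code_id), collapse = ", "),
         " (supported: \"standard\", \"plastid\", \"11\")", call. = FALSE)
  }
  tab <- Biostrings::GENETIC_CODE
  codons <- names(tab)

  stop_codons <- codons[tab == "*"]
  aa <- tab[tab != "*"]
  single <- names(table(aa))[table(aa) == 1L]          # M, W
  excluded_single <- codons[tab %in% single]           # ATG, TGG

  fam_aa <- sort(setdiff(unique(aa), single))
  families <- lapply(fam_aa, function(a) sort(codons[tab == a]))
  names(families) <- fam_aa
  degeneracy <- vapply(families, length, integer(1))

  analysis_codons <- sort(unlist(families, use.names = FALSE))

  deg_classes <- split(names(degeneracy), degeneracy)

  structure(
    list(
      code_id = code_id,
      codon_table = tab,
      family_of = tab,
      families = families,
      degeneracy = degeneracy,
      deg_classes = deg_classes,
      analysis_codons = analysis_codons,
      stop_codons = stop_codons,
      excluded_single_codons = excluded_single
    ),
    class = "codon_space"
  )
}

#' @export
print.codon_space <- function(x, ...) {
  cat("<codon_space> code:", x$code_id, "\n")
  cat(" ", length(x$analysis_codons), "analysis codons in",
      length(x$families), "synonymous families\n")
  cls <- vapply(x$deg_classes, length, integer(1))
  cat("  degeneracy classes:",
      paste(sprintf("%s-fold x %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

is_codon_space <- function(x) inherits(x, "codon_space")

assert_codon_space <- function(x) {
  if (!is_codon_space(x)) stop("expected a codon_space object", call. = FALSE)
  invisible(x)
}
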