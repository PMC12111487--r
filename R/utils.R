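clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a TSV file
#'
#' UTF-8, tab-delimited, '.' decimal separator, no quoting, no row names.
#' Used for all tabular outputs so that every figure has a plain-text twin.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# split a coding sequence into its codons (assumes length divisible by 3)
split_codons <- function(sequence) {
  n <- nchar(sequence)
  substring(sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Count codons in a coding sequence
#'
#' Non-overlapping trinucleotide counts in frame 1, over the 64 unambiguous
#' codons. The vector always has all 64 codons as names, in alphabetical
#' order; codons containing ambiguity codes are not counted.
#'
#' @param sequence A single DNA string (character or `DNAString`).
#' @return Named integer vector of length 64.
#' @export
codon_counts <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  Biostrings::oligonucleotideFrequency(sequence, width = 3L, step = 3L)
}

# Accept a cds_set, a counts matrix, or a single named counts vector and
# return a genes x 64 counts matrix.
as_counts_matrix <- function(x) {
  if (inherits(x, "cds_set")) return(x$counts)
  if (is.matrix(x)) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    m <- matrix(x, nrow = 1L, dimnames = list("gene_1", names(x)))
    return(m)
  }
  stop("expected a cds_set, a codon-count matrix, or a named count vector",
       call. = FALSE)
}

# Expand a (possibly partial) named count vector to the full 64-codon basis.
full_counts <- function(counts) {
  if (is.null(names(counts))) {
    stop("codon counts must be named by codon", call. = FALSE)
  }
  all64 <- names(Biostrings::GENETIC_CODE)
  out <- stats::setNames(numeric(64L), all64)
  keep <- intersect(names(counts), all64)
  out[keep] <- counts[keep]
  out
}
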