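#' Extract raw CDS sequences from a GenBank or FASTA file
#'
#' GenBank flat files are scanned for `CDS` features; locations with
#' `complement()` and `join()` are honoured (exons concatenated in location
#' order, then reverse-complemented when the whole location is on the minus
#' strand), so every returned sequence is in 5'-to-3' coding orientation.
#' Features whose location carries a partial marker (`<` or `>`) are
#' returned tagged as partial so the filter can reject them. Multi-FASTA
#' input is treated as pre-extracted CDSs (no location metadata, so nothing
#' is flagged partial).
#'
#' @param path Path to a `.gb`/`.gbk` GenBank flat file or a FASTA file.
#' @param genome_id Label for the genome; defaults to the file name without
#'   extension.
#' @return A data frame with columns `cds_id`, `genome_id`, `sequence`
#'   (uppercase DNA), and `partial` (logical).
#' @export
extract_cds <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))

  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines) == 0L) stop("empty input file: ", path, call. = FALSE)

  if (startsWith(head_lines[[1L]], ">")) {
    dss <- Biostrings::readDNAStringSet(path)
    if (length(dss) == 0L) stop("no sequences found in FASTA: ", path, call. = FALSE)
    ids <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
    out <- data.frame(
      cds_id = make.unique(ids, sep = "_"),
      genome_id = genome_id,
      sequence = toupper(as.character(dss)),
      partial = FALSE,
      stringsAsFactors = FALSE
    )
  } else if (any(grepl("^LOCUS", head_lines))) {
    out <- parse_genbank_cds(path, genome_id)
  } else {
    stop("cannot parse input (neither FASTA nor GenBank): ", path, call. = FALSE)
  }
  if (nrow(out) == 0L) stop("no CDS features found in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}

# Minimal GenBank flat-file CDS reader: LOCUS / FEATURES / ORIGIN sections,
# CDS locations with join()/complement() nesting and partial markers.
parse_genbank_cds <- function(path, genome_id) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0L) stop("no LOCUS line in ", path, call. = FALSE)
  rec_ends <- c(rec_starts[-1L] - 1L, length(lines))

  res <- list()
  for (r in seq_along(rec_starts)) {
    rl <- lines[rec_starts[r]:rec_ends[r]]
    origin_at <- grep("^ORIGIN", rl)
    feat_at <- grep("^FEATURES", rl)
    if (length(feat_at) == 0L || length(origin_at) == 0L) next
    end_at <- grep("^//\\s*$", rl)
    end_at <- if (length(end_at)) end_at[[1L]] else length(rl) + 1L

    seq_lines <- rl[(origin_at[[1L]] + 1L):(end_at - 1L)]
    genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

    feat_lines <- rl[(feat_at[[1L]] + 1L):(origin_at[[1L]] - 1L)]
    key_idx <- grep("^ {5}\\S", feat_lines)
    if (length(key_idx) == 0L) next
    key_end <- c(key_idx[-1L] - 1L, length(feat_lines))

    for (i in seq_along(key_idx)) {
      block <- feat_lines[key_idx[i]:key_end[i]]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[[1L]])
      if (key != "CDS") next

      # location may continue over lines until the first qualifier
      qual_at <- grep("^ {21}/", block)
      loc_end <- if (length(qual_at)) qual_at[[1L]] - 1L else length(block)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", block[[1L]]),
                            block[seq_len(loc_end)[-1L]])), collapse = "")
      qual <- block[grep("^ {21}/", block)]
      name <- gb_qualifier(qual, "gene") %||%
        gb_qualifier(qual, "locus_tag") %||%
        gb_qualifier(qual, "product") %||%
        sprintf("cds_%03d", length(res) + 1L)

      sp <- gb_splice(loc, genome_seq)
      res[[length(res) + 1L]] <- data.frame(
        cds_id = name, genome_id = genome_id, sequence = sp$sequence,
        partial = sp$partial, stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) {
    return(data.frame(cds_id = character(), genome_id = character(),
                      sequence = character(), partial = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$cds_id <- make.unique(out$cds_id, sep = "_")
  out
}

gb_qualifier <- function(qual_lines, name) {
  pat <- paste0("^ {21}/", name, "=")
  hit <- grep(pat, qual_lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  v <- sub(pat, "", hit[[1L]])
  gsub("\"", "", trimws(v))
}

# Splice a GenBank location string against the full record sequence.
gb_splice <- function(loc, genome_seq) {
  partial <- grepl("[<>]", loc)
  loc2 <- gsub("[<>]", "", gsub("\\s+", "", loc))
  minus <- FALSE
  if (grepl("^complement\\(", loc2)) {
    minus <- TRUE
    loc2 <- sub("^complement\\((.*)\\)$", "\\1", loc2)
  }
  if (grepl("^join\\(", loc2)) {
    loc2 <- sub("^join\\((.*)\\)$", "\\1", loc2)
  }
  spans <- strsplit(loc2, ",")[[1L]]
  pieces <- vapply(spans, function(sp) {
    sp_minus <- FALSE
    if (grepl("^complement\\(", sp)) {        # per-exon strand (rare)
      sp_minus <- TRUE
      sp <- sub("^complement\\((.*)\\)$", "\\1", sp)
    }
    m <- regmatches(sp, regexec("^(\\d+)(\\.\\.(\\d+))?$", sp))[[1L]]
    if (length(m) == 0L) stop("unparsable GenBank location: ", sp, call. = FALSE)
    a <- as.integer(m[[2L]])
    b <- if (nzchar(m[[4L]] %||% "")) as.integer(m[[4L]]) else a
    piece <- substr(genome_seq, a, b)
    if (sp_minus) piece <- revcomp(piece)
    piece
  }, character(1))
  sequence <- paste(pieces, collapse = "")
  if (minus) sequence <- revcomp(sequence)
  list(sequence = sequence, partial = partial)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Rejection reasons in precedence order: a multiply-faulty sequence is
# tallied under the first reason that applies.
.rejection_reasons <- c("partial", "not_multiple_of_3", "short",
                        "no_atg_start", "no_stop_end", "internal_stop",
                        "ambiguous_base")

#' Quality-filter raw CDS sequences
#'
#' Applies the standard CDS quality criteria for codon usage analysis:
#' length at least `min_length` nt and divisible by three, ATG start, a
#' terminal stop codon (TAA/TAG/TGA), no internal stop codon, and no
#' ambiguous nucleotides. Features tagged partial are rejected outright.
#' Each rejected sequence is tallied under exactly one reason, checked in
#' the order partial, not_multiple_of_3, short, no_atg_start, no_stop_end,
#' internal_stop, ambiguous_base. Rejections are reported, never raised.
#'
#' Duplicated genes (for example from inverted repeats) are not
#' deduplicated: every feature passing the filters is kept.
#'
#' @param raw A data frame as returned by [extract_cds()], or a character
#'   vector of uppercase DNA sequences (then treated as non-partial).
#' @param space A [build_codon_space()] object.
#' @param genome_id Genome label used when `raw` is a bare character vector.
#' @param min_length Minimum CDS length in nt (default 300).
#' @return An object of class `cds_set`: list with `genes` (data frame:
#'   `gene_id`, `genome_id`, `length_nt`, `l_aa`, `sequence`), `counts`
#'   (genes x 64 codon-count matrix, terminal stop and start included so
#'   each row sums to `length_nt/3`), and `report` (one-row data frame:
#'   `genome_id`, `n_raw`, `n_pass`, one column per rejection reason).
#' @export
filter_cds <- function(raw, space = build_codon_space(), genome_id = "genome",
                       min_length = 300L) {
  assert_codon_space(space)
  if (is.character(raw)) {
    raw <- data.frame(
      cds_id = sprintf("gene_%03d", seq_along(raw)),
      genome_id = genome_id,
      sequence = toupper(raw),
      partial = FALSE,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(raw), all(c("sequence") %in% names(raw)))
  if (is.null(raw$partial)) raw$partial <- FALSE
  if (is.null(raw$cds_id)) raw$cds_id <- sprintf("gene_%03d", seq_len(nrow(raw)))
  if (is.null(raw$genome_id)) raw$genome_id <- genome_id
  genome_id <- if (nrow(raw)) raw$genome_id[[1L]] else genome_id

  stops <- space$stop_codons
  tally <- stats::setNames(integer(length(.rejection_reasons)), .rejection_reasons)
  keep <- logical(nrow(raw))

  for (i in seq_len(nrow(raw))) {
    s <- raw$sequence[[i]]
    n <- nchar(s)
    reason <- NULL
    if (isTRUE(raw$partial[[i]])) {
      reason <- "partial"
    } else if (n %% 3L != 0L) {
      reason <- "not_multiple_of_3"
    } else if (n < min_length) {
      reason <- "short"
    } else if (substr(s, 1L, 3L) != "ATG") {
      reason <- "no_atg_start"
    } else if (!substr(s, n - 2L, n) %in% stops) {
      reason <- "no_stop_end"
    } else {
      codons <- split_codons(s)
      internal <- codons[-length(codons)]
      if (any(internal %in% stops)) {
        reason <- "internal_stop"
      } else if (grepl("[^ACGT]", s)) {
        reason <- "ambiguous_base"
      }
    }
    if (is.null(reason)) keep[i] <- TRUE else tally[reason] <- tally[reason] + 1L
  }

  genes <- raw[keep, , drop = FALSE]
  codon_names <- sort(names(Biostrings::GENETIC_CODE))
  counts <- matrix(0L, nrow = nrow(genes), ncol = 64L,
                   dimnames = list(genes$cds_id, codon_names))
  if (nrow(genes)) {
    cm <- t(vapply(genes$sequence, function(s) codon_counts(s)[codon_names],
                   integer(64L), USE.NAMES = FALSE))
    counts[] <- cm
  }

  genes_df <- data.frame(
    gene_id = genes$cds_id,
    genome_id = genes$genome_id,
    length_nt = nchar(genes$sequence),
    l_aa = nchar(genes$sequence) / 3L - 1L,
    sequence = genes$sequence,
    stringsAsFactors = FALSE
  )
  rownames(genes_df) <- NULL

  report <- data.frame(genome_id = genome_id, n_raw = nrow(raw),
                       n_pass = sum(keep), stringsAsFactors = FALSE)
  for (r in .rejection_reasons) report[[r]] <- tally[[r]]

  structure(list(genes = genes_df, counts = counts, report = report),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("<cds_set>", x$report$genome_id, "-", nrow(x$genes), "of",
      x$report$n_raw, "CDSs pass filters\n")
  invisible(x)
}

#' Write the filtered CDSs of a `cds_set` as FASTA
#'
#' @param x A `cds_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path) {
  stopifnot(inherits(x, "cds_set"))
  dss <- Biostrings::DNAStringSet(x$genes$sequence)
  names(dss) <- x$genes$gene_id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
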