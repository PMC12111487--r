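#' Relative synonymous codon usage (RSCU)
#'
#' For codon j in a synonymous family of size k with family total N > 0,
#' RSCU_j = x_j / (N / k): observed count over the count expected under
#' uniform usage within the family. Families with zero observations are
#' returned all-zero and listed in the `zero_families` attribute.
#'
#' @param counts Named codon-count vector.
#' @param space A [build_codon_space()] object.
#' @return Named numeric over the 59 analysis codons, with attribute
#'   `zero_families` (character vector of unobserved amino-acid families).
#'   Within each observed family the values sum to the family degeneracy k.
#' @examples
#' rscu(c(TTT = 3, TTC = 1))[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(counts, space = build_codon_space()) {
  assert_codon_space(space)
  counts <- full_counts(counts)
  if (sum(counts[space$analysis_codons]) < 1) {
    stop("undefined statistic: no codons in the analysis set", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(space$analysis_codons)),
                         space$analysis_codons)
  zero_fams <- character()
  for (aa in names(space$families)) {
    cods <- space$families[[aa]]
    x <- counts[cods]
    N <- sum(x)
    if (N == 0) {
      zero_fams <- c(zero_fams, aa)
      out[cods] <- 0
    } else {
      out[cods] <- x / (N / length(cods))
    }
  }
  attr(out, "zero_families") <- zero_fams
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Per synonymous family with n >= 2 counted codons, the bias-corrected
#' homozygosity is F = (n * sum(p^2) - 1) / (n - 1) with p the
#' within-family codon proportions. Class means F2, F3, F4, F6 are taken
#' over the usable families of each degeneracy class (9 two-fold, the
#' three-fold Ile, 5 four-fold, and the three six-fold families Leu, Ser,
#' Arg treated whole), and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61.
#'
#' Families with n < 2 or F <= 0 are unusable and excluded from their
#' class mean. A class with no usable family is imputed: F3 as
#' (F2 + F4)/2 when both neighbours exist, any other missing class as the
#' mean of the available class means. `n_classes_imputed` records how many
#' class means were imputed.
#'
#' @inheritParams rscu
#' @return Object of class `enc_result`: list with `f_bar` (named by class
#'   "2","3","4","6"), `enc_raw`, `enc_obs` (capped to \[20, 61\]), and
#'   `n_classes_imputed`.
#' @export
enc <- function(counts, space = build_codon_space()) {
  assert_codon_space(space)
  counts <- full_counts(counts)

  f_hat <- stats::setNames(rep(NA_real_, length(space$families)),
                           names(space$families))
  for (aa in names(space$families)) {
    x <- counts[space$families[[aa]]]
    n <- sum(x)
    if (n >= 2) {
      p <- x / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) f_hat[aa] <- f
    }
  }

  classes <- c("2", "3", "4", "6")
  f_bar <- stats::setNames(rep(NA_real_, 4L), classes)
  for (k in classes) {
    fams <- space$deg_classes[[k]]
    vals <- f_hat[fams]
    if (any(!is.na(vals))) f_bar[k] <- mean(vals, na.rm = TRUE)
  }
  if (all(is.na(f_bar))) {
    stop("undefined statistic: no usable synonymous family for ENC",
         call. = FALSE)
  }

  n_imputed <- 0L
  if (is.na(f_bar[["3"]]) && !is.na(f_bar[["2"]]) && !is.na(f_bar[["4"]])) {
    f_bar[["3"]] <- (f_bar[["2"]] + f_bar[["4"]]) / 2
    n_imputed <- n_imputed + 1L
  }
  still <- is.na(f_bar)
  if (any(still)) {
    f_bar[still] <- mean(f_bar[!still])
    n_imputed <- n_imputed + sum(still)
  }

  n_fam <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  enc_raw <- 2 + sum(n_fam / f_bar)
  structure(
    list(f_bar = f_bar, enc_raw = enc_raw,
         enc_obs = clamp(enc_raw, 20, 61),
         n_classes_imputed = n_imputed),
    class = "enc_result"
  )
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<enc_result> ENC = %.3f (raw %.3f, %d class(es) imputed)\n",
              x$enc_obs, x$enc_raw, x$n_classes_imputed))
  invisible(x)
}

#' Effective number of codons for every gene of a CDS set
#'
#' @param x A `cds_set` or counts matrix.
#' @param space A [build_codon_space()] object.
#' @return Named numeric of ENC values (NA where ENC is undefined).
#' @export
enc_per_gene <- function(x, space = build_codon_space()) {
  m <- as_counts_matrix(x)
  vapply(seq_len(nrow(m)), function(i) {
    tryCatch(enc(m[i, ], space)$enc_obs, error = function(e) NA_real_)
  }, numeric(1)) |> stats::setNames(rownames(m))
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness w of every analysis-codon
#' occurrence in the gene (Met, Trp, and stops excluded). Reference codons
#' with missing, zero or negative w receive the floor `w_floor` so the
#' geometric mean stays defined.
#'
#' @param counts Named codon-count vector.
#' @param reference_w Named numeric of relative adaptiveness values, scaled
#'   so the best codon of each family has w = 1 (see
#'   [reference_w_from_high_set()]).
#' @param space A [build_codon_space()] object.
#' @param w_floor Floor applied to unusable w values (default 0.01).
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, reference_w, space = build_codon_space(),
                w_floor = 0.01) {
  assert_codon_space(space)
  if (length(reference_w) == 0L || is.null(names(reference_w))) {
    stop("configuration error: reference_w must be a named, non-empty vector",
         call. = FALSE)
  }
  counts <- full_counts(counts)[space$analysis_codons]
  total <- sum(counts)
  if (total < 1) {
    stop("undefined statistic: no analysis codons in gene", call. = FALSE)
  }
  w <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  w[names(reference_w)[names(reference_w) %in% names(w)]] <-
    reference_w[names(reference_w) %in% names(w)]
  w[is.na(w) | w <= 0] <- w_floor
  used <- counts > 0
  exp(sum(counts[used] * log(w[used])) / total)
}

#' Relative adaptiveness from a putative highly expressed gene set
#'
#' Pools the codon counts of the given genes, computes RSCU, and rescales
#' within each family by the family maximum: w_j = RSCU_j / max RSCU.
#' Codons unobserved in the reference (including whole unobserved families)
#' get the floor.
#'
#' @param high_genes A `cds_set`, counts matrix, or single named count
#'   vector for the reference genes.
#' @param space A [build_codon_space()] object.
#' @param w_floor Floor for unobserved codons.
#' @return Named numeric w over the 59 analysis codons, family maxima 1.
#' @export
reference_w_from_high_set <- function(high_genes, space = build_codon_space(),
                                      w_floor = 0.01) {
  assert_codon_space(space)
  m <- as_counts_matrix(high_genes)
  if (nrow(m) < 1L) stop("need at least one reference gene", call. = FALSE)
  pooled <- colSums(m)
  r <- rscu(pooled, space)
  w <- stats::setNames(rep(w_floor, length(r)), names(r))
  for (aa in names(space$families)) {
    cods <- space$families[[aa]]
    mx <- max(r[cods])
    if (mx > 0) w[cods] <- pmax(r[cods] / mx, w_floor)
  }
  w
}

#' Codon bias index (CBI)
#'
#' Excess usage of a designated optimal-codon set relative to random
#' expectation, scaled to \[-1, 1\]:
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_tot counts codons in
#' families containing at least one optimal codon, N_opt counts optimal
#' codon occurrences, and N_ran = sum over those families of
#' N_family * m_family / k_family (m = optimal codons in the family).
#'
#' @param counts Named codon-count vector.
#' @param optimal Character vector of optimal codons (non-empty).
#' @param space A [build_codon_space()] object.
#' @return CBI in \[-1, 1\].
#' @export
cbi <- function(counts, optimal, space = build_codon_space()) {
  assert_codon_space(space)
  if (length(optimal) == 0L) {
    stop("configuration error: optimal codon set is empty", call. = FALSE)
  }
  counts <- full_counts(counts)
  n_tot <- 0; n_opt <- 0; n_ran <- 0
  for (aa in names(space$families)) {
    cods <- space$families[[aa]]
    m_f <- sum(cods %in% optimal)
    if (m_f == 0L) next
    N_f <- sum(counts[cods])
    n_tot <- n_tot + N_f
    n_opt <- n_opt + sum(counts[intersect(cods, optimal)])
    n_ran <- n_ran + N_f * m_f / length(cods)
  }
  if (abs(n_tot - n_ran) < .Machine$double.eps * 64) {
    stop("undefined statistic: degenerate CBI denominator", call. = FALSE)
  }
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' High-frequency codons of a pooled RSCU table
#'
#' @param pooled_rscu Named RSCU vector (genome-level, from [rscu()]).
#' @return Character vector of codons with RSCU > 1.
#' @export
high_frequency_codons <- function(pooled_rscu) {
  names(pooled_rscu)[pooled_rscu > 1]
}

#' Optimal codon identification by the ENC-decile delta-RSCU rule
#'
#' Genes are ranked by ENC; the decile with the lowest ENC (strongest
#' bias) is taken as the putative high-expression group and the decile
#' with the highest ENC as the low-expression group (`high_group =
#' "high_enc"` swaps the mapping). Group size is `ceiling(decile * n)`
#' genes; ENC ties are broken by gene id. RSCU is pooled within each group
#' and delta-RSCU = RSCU_high - RSCU_low computed per codon; optimal
#' codons satisfy RSCU_high > 1 (or whole-set RSCU > 1 when `rscu_scope =
#' "all_genes"`) and delta-RSCU > `delta_threshold`. Genes with undefined
#' ENC are excluded (recorded in `n_enc_undefined`).
#'
#' @param x A `cds_set` or genes x 64 counts matrix (>= 10 genes).
#' @param space A [build_codon_space()] object.
#' @param decile Fraction of genes per group (default 0.10).
#' @param delta_threshold delta-RSCU cutoff (default 0.08).
#' @param high_group Which ENC extreme is the high-expression group.
#' @param rscu_scope Where the "RSCU > 1" condition is evaluated.
#' @return List of class `optimal_codon_result`: `high_group`, `low_group`
#'   (gene ids), `rscu_high`, `rscu_low`, `delta_rscu`, `optimal_codons`,
#'   `high_frequency_codons` (RSCU > 1 in the high group),
#'   `n_enc_undefined`.
#' @export
optimal_codons <- function(x, space = build_codon_space(), decile = 0.10,
                           delta_threshold = 0.08,
                           high_group = c("low_enc", "high_enc"),
                           rscu_scope = c("high_group", "all_genes")) {
  assert_codon_space(space)
  high_group <- match.arg(high_group)
  rscu_scope <- match.arg(rscu_scope)
  m <- as_counts_matrix(x)
  e <- enc_per_gene(m, space)
  undef <- is.na(e)
  m <- m[!undef, , drop = FALSE]
  e <- e[!undef]
  n <- nrow(m)
  if (n < 10L) {
    stop("insufficient data: need at least 10 genes with defined ENC",
         call. = FALSE)
  }
  size <- ceiling(decile * n)
  ord <- order(e, rownames(m))
  low_enc_ids <- rownames(m)[ord][seq_len(size)]
  high_enc_ids <- rev(rownames(m)[ord])[seq_len(size)]
  if (high_group == "low_enc") {
    hi <- low_enc_ids; lo <- high_enc_ids
  } else {
    hi <- high_enc_ids; lo <- low_enc_ids
  }
  r_hi <- rscu(colSums(m[hi, , drop = FALSE]), space)
  r_lo <- rscu(colSums(m[lo, , drop = FALSE]), space)
  delta <- r_hi - r_lo
  gate <- if (rscu_scope == "high_group") r_hi else rscu(colSums(m), space)
  opt <- names(delta)[gate > 1 & delta > delta_threshold]
  structure(
    list(genome_id = attr(x, "genome_id") %||% NA_character_,
         high_group = hi, low_group = lo,
         rscu_high = r_hi, rscu_low = r_lo, delta_rscu = delta,
         optimal_codons = opt,
         high_frequency_codons = high_frequency_codons(r_hi),
         n_enc_undefined = sum(undef)),
    class = "optimal_codon_result"
  )
}

#' @export
print.optimal_codon_result <- function(x, ...) {
  cat("<optimal_codon_result>", length(x$optimal_codons), "optimal codons:",
      paste(x$optimal_codons, collapse = " "), "\n")
  invisible(x)
}

#' Per-gene index summary (ENC, CAI, CBI, GC3s, L_aa)
#'
#' Computes the per-gene index table for a filtered CDS set. The CAI
#' reference is derived from the genome's own putative high-expression
#' group (the low-ENC decile) via [reference_w_from_high_set()], and the
#' CBI optimal set defaults to the codons identified by
#' [optimal_codons()]; both can be overridden.
#'
#' @param x A `cds_set`.
#' @param space A [build_codon_space()] object.
#' @param reference_w Optional CAI reference (named w vector).
#' @param optimal Optional optimal codon set for CBI.
#' @param decile,delta_threshold Passed to [optimal_codons()] when
#'   defaults are derived.
#' @return Data frame: `gene_id`, `enc`, `cai`, `cbi`, `gc3s`, `l_aa`.
#' @export
index_summary <- function(x, space = build_codon_space(), reference_w = NULL,
                          optimal = NULL, decile = 0.10,
                          delta_threshold = 0.08) {
  stopifnot(inherits(x, "cds_set"))
  m <- x$counts
  e <- enc_per_gene(m, space)
  oc <- NULL
  if (is.null(reference_w) || is.null(optimal)) {
    oc <- optimal_codons(x, space, decile = decile,
                         delta_threshold = delta_threshold)
  }
  if (is.null(reference_w)) {
    reference_w <- reference_w_from_high_set(
      m[oc$high_group, , drop = FALSE], space)
  }
  if (is.null(optimal)) optimal <- oc$optimal_codons
  cai_v <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(cai(m[i, ], reference_w, space), error = function(e) NA_real_)
  }, numeric(1))
  cbi_v <- if (length(optimal)) {
    vapply(seq_len(nrow(m)), function(i) {
      tryCatch(cbi(m[i, ], optimal, space), error = function(e) NA_real_)
    }, numeric(1))
  } else rep(NA_real_, nrow(m))
  gc3s_v <- vapply(seq_len(nrow(m)), function(i) gc3s(m[i, ], space), numeric(1))
  data.frame(
    gene_id = x$genes$gene_id,
    enc = unname(e), cai = cai_v, cbi = cbi_v, gc3s = gc3s_v,
    l_aa = x$genes$l_aa,
    stringsAsFactors = FALSE
  )
}
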