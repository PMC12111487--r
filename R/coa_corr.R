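#' Correspondence analysis of a genes x codons matrix
#'
#' Standard (chi-square metric) correspondence analysis via singular value
#' decomposition: with P the matrix divided by its grand total, r and c
#' its margins, the standardised residual matrix
#' S = D_r^{-1/2} (P - r c^T) D_c^{-1/2} is decomposed as S = U D V^T;
#' principal row coordinates are D_r^{-1/2} U D and column coordinates
#' D_c^{-1/2} V D. Each axis carries inertia sigma_k^2, reported as a
#' percentage of the total; axes are ordered by decreasing inertia.
#' All-zero columns are dropped (recorded in `dropped_columns`); a matrix
#' whose rows are all proportional yields a degenerate result with zero
#' informative axes. Axis signs are fixed deterministically so that the
#' largest-magnitude column score on each axis is positive (CA axes are
#' sign-indeterminate); [axis1_correlations()] can reflect Axis 1 again to
#' anchor it to GC3s.
#'
#' @param m Non-negative matrix, typically the per-gene RSCU matrix (rows
#'   = genes, columns = the 59 analysis codons). Raw codon counts work
#'   too.
#' @return Object of class `ca_result`: list with `row_scores` (genes x
#'   n_axes), `col_scores`, `sv` (singular values), `inertia`,
#'   `inertia_pct` (sums to 100 when total inertia > 0), `total_inertia`,
#'   `n_axes`, `dropped_columns`.
#' @export
correspondence_analysis <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("matrix must be non-negative and finite", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("row_%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("col_%d", seq_len(ncol(m)))
  zero_col <- colSums(m) == 0
  dropped <- colnames(m)[zero_col]
  m <- m[, !zero_col, drop = FALSE]
  if (any(rowSums(m) == 0)) {
    stop("matrix has all-zero rows after dropping empty columns",
         call. = FALSE)
  }
  grand <- sum(m)
  P <- m / grand
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- max(dim(m)) * max(sv$d, 0) * .Machine$double.eps * 100
  keep <- which(sv$d > tol)
  n_axes <- length(keep)

  if (n_axes == 0L) {
    return(structure(
      list(row_scores = matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL)),
           col_scores = matrix(0, ncol(m), 0, dimnames = list(colnames(m), NULL)),
           sv = numeric(0), inertia = numeric(0), inertia_pct = numeric(0),
           total_inertia = 0, n_axes = 0L, dropped_columns = dropped),
      class = "ca_result"))
  }

  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|.| column loading positive per axis
  for (k in seq_len(n_axes)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  row_scores <- sweep(U, 1L, sqrt(r), "/") %*% diag(d, n_axes)
  col_scores <- sweep(V, 1L, sqrt(cc), "/") %*% diag(d, n_axes)
  dimnames(row_scores) <- list(rownames(m), paste0("Axis", seq_len(n_axes)))
  dimnames(col_scores) <- list(colnames(m), paste0("Axis", seq_len(n_axes)))
  inertia <- d^2
  structure(
    list(row_scores = row_scores, col_scores = col_scores, sv = d,
         inertia = inertia, inertia_pct = 100 * inertia / sum(inertia),
         total_inertia = sum(inertia), n_axes = n_axes,
         dropped_columns = dropped),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat("<ca_result>", nrow(x$row_scores), "rows,", x$n_axes, "axes\n")
  if (x$n_axes > 0) {
    k <- min(4L, x$n_axes)
    cat("  inertia %:",
        paste(sprintf("%.2f", x$inertia_pct[seq_len(k)]), collapse = ", "),
        if (x$n_axes > k) "..." else "", "\n")
  }
  invisible(x)
}

#' Correlations of CA Axis 1 with composition and bias indices
#'
#' Correlates the Axis-1 row scores with each supplied per-gene variable,
#' and adds the inter-variable pairs commonly reported alongside (GC3 vs
#' GC1, GC3 vs GC2, GC1 vs GC2) when those columns are present. Axis 1 is
#' reflected, if necessary, so its correlation with `align_to` is
#' non-negative (recorded in the `axis_reflected` attribute) -- CA axes
#' are sign-indeterminate and this makes correlation signs reproducible.
#' Raw two-sided p-values are reported together with Benjamini-Hochberg
#' adjusted values. A constant variable yields an NA coefficient flagged
#' `undefined`, not an error.
#'
#' @param ca A [correspondence_analysis()] result (n_axes >= 1).
#' @param per_gene Data frame of per-gene variables, rows aligned with
#'   `ca$row_scores` (matched by rownames of the score matrix against a
#'   `gene_id` column when present, else by position). Typical columns:
#'   `gc1`, `gc2`, `gc3`, `gc3s`, `gc_all`, `cai`, `cbi`, `enc`, `l_aa`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param align_to Column used to anchor the Axis-1 sign (default
#'   `"gc3s"`; skipped when absent).
#' @return Data frame: `var_a`, `var_b`, `method`, `estimate`, `p_value`,
#'   `p_adj`, `undefined`; attribute `axis_reflected`.
#' @export
axis1_correlations <- function(ca, per_gene, method = c("spearman", "pearson"),
                               align_to = "gc3s") {
  method <- match.arg(method)
  stopifnot(inherits(ca, "ca_result"))
  if (ca$n_axes < 1L) stop("CA result has no informative axes", call. = FALSE)
  vars <- per_gene
  if (!is.null(vars$gene_id)) {
    idx <- match(rownames(ca$row_scores), vars$gene_id)
    vars <- vars[idx, , drop = FALSE]
    vars$gene_id <- NULL
  }
  vars <- vars[, vapply(vars, is.numeric, logical(1)), drop = FALSE]
  if (nrow(vars) < 3L) stop("insufficient data: need >= 3 genes", call. = FALSE)

  axis1 <- ca$row_scores[, 1L]
  reflected <- FALSE
  if (!is.null(align_to) && align_to %in% names(vars)) {
    a <- vars[[align_to]]
    if (stats::sd(a, na.rm = TRUE) > 0) {
      rho <- suppressWarnings(stats::cor(axis1, a, method = method,
                                         use = "complete.obs"))
      if (is.finite(rho) && rho < 0) { axis1 <- -axis1; reflected <- TRUE }
    }
  }

  one_pair <- function(a, b, na, nb) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(data.frame(var_a = na, var_b = nb, method = method,
                        estimate = NA_real_, p_value = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = method,
                                           exact = FALSE))
    data.frame(var_a = na, var_b = nb, method = method,
               estimate = unname(ct$estimate), p_value = ct$p.value,
               undefined = FALSE, stringsAsFactors = FALSE)
  }

  rows <- lapply(names(vars), function(v)
    one_pair(axis1, vars[[v]], "Axis1", v))
  extra <- list(c("gc3", "gc1"), c("gc3", "gc2"), c("gc1", "gc2"))
  for (pr in extra) {
    if (all(pr %in% names(vars))) {
      rows[[length(rows) + 1L]] <-
        one_pair(vars[[pr[1L]]], vars[[pr[2L]]], pr[1L], pr[2L])
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("var_a", "var_b", "method", "estimate", "p_value",
                 "p_adj", "undefined")]
  attr(out, "axis_reflected") <- reflected
  out
}
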