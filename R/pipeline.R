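#' Analysis configuration
#'
#' Collects the dialect switches and thresholds used across the pipeline.
#' The strong-bias convention is ENC < 35; group membership for the
#' optimal-codon rule is the low-ENC decile by default.
#'
#' @param synonymous_only Third-position dialect for A3/T3/C3/G3 and PR2.
#' @param decile Fraction of genes per expression group.
#' @param delta_threshold delta-RSCU cutoff for optimal codons.
#' @param enc_strong_threshold ENC below which a gene counts as strongly
#'   biased.
#' @param neutrality_orientation `"gc12_x"` (x = GC12, y = GC3) or
#'   `"gc3_x"`.
#' @param high_group `"low_enc"` or `"high_enc"`.
#' @param rscu_scope Where the RSCU > 1 gate of the optimal-codon rule is
#'   evaluated.
#' @param cor_method Correlation method for Axis-1 follow-up.
#' @param w_floor CAI floor for unobserved reference codons.
#' @param min_length Minimum CDS length (nt) for the filter.
#' @param seed Optional seed recorded in the fingerprint.
#' @return List of class `cub_config` with a `fingerprint` string.
#' @export
cub_config <- function(synonymous_only = TRUE, decile = 0.10,
                       delta_threshold = 0.08, enc_strong_threshold = 35,
                       neutrality_orientation = c("gc12_x", "gc3_x"),
                       high_group = c("low_enc", "high_enc"),
                       rscu_scope = c("high_group", "all_genes"),
                       cor_method = c("spearman", "pearson"),
                       w_floor = 0.01, min_length = 300L, seed = NULL) {
  stopifnot(decile > 0, decile <= 0.5, delta_threshold > 0,
            enc_strong_threshold > 0)
  cfg <- list(
    synonymous_only = synonymous_only, decile = decile,
    delta_threshold = delta_threshold,
    enc_strong_threshold = enc_strong_threshold,
    neutrality_orientation = match.arg(neutrality_orientation),
    high_group = match.arg(high_group),
    rscu_scope = match.arg(rscu_scope),
    cor_method = match.arg(cor_method),
    w_floor = w_floor, min_length = as.integer(min_length), seed = seed
  )
  cfg$fingerprint <- paste(
    vapply(names(cfg), function(k) paste0(k, "=", format(cfg[[k]] %||% "NULL")),
           character(1)),
    collapse = ";")
  structure(cfg, class = "cub_config")
}

resolve_cds_set <- function(input, genome_id, space, config) {
  if (inherits(input, "cds_set")) return(input)
  if (inherits(input, "synthetic_genome")) {
    return(filter_cds(unname(input$sequences), space,
                      genome_id = genome_id %||% input$genome_id,
                      min_length = config$min_length))
  }
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    raw <- extract_cds(input, genome_id = genome_id)
    return(filter_cds(raw, space, min_length = config$min_length))
  }
  if (is.character(input)) {
    return(filter_cds(input, space, genome_id = genome_id %||% "genome",
                      min_length = config$min_length))
  }
  stop("unsupported input: expected file path, sequences, cds_set, or ",
       "synthetic_genome", call. = FALSE)
}

#' Run the full codon-usage-bias analysis for one genome
#'
#' Executes the whole per-genome pipeline: CDS extraction and filtering,
#' composition statistics (both dialects), RSCU, ENC/CAI/CBI, optimal
#' codons, the ENC-plot/PR2/neutrality diagnostics, and correspondence
#' analysis with Axis-1 correlations. Genes with undefined ENC are
#' excluded from ENC-based summaries and logged.
#'
#' @param input File path (GenBank or FASTA), character vector of CDS
#'   sequences, a `cds_set`, or a `synthetic_genome`.
#' @param genome_id Genome label (defaults from the input).
#' @param space A [build_codon_space()] object.
#' @param config A [cub_config()].
#' @return Object of class `genome_result`: list with `genome_id`,
#'   `config`, `cds` (the `cds_set`), `filter_report`, `gene_composition`,
#'   `genome_composition`, `table1_row`, `rscu_pooled`, `rscu_matrix`
#'   (genes x 59), `high_frequency_codons`, `optimal` (from
#'   [optimal_codons()]), `indices` (per-gene), `diagnostics`,
#'   `enc_ratio_hist`, `neutrality`, `table2_row`, `ca`, `correlations`.
#' @export
run_genome <- function(input, genome_id = NULL, space = build_codon_space(),
                       config = cub_config()) {
  cds <- resolve_cds_set(input, genome_id, space, config)
  genome_id <- genome_id %||% cds$report$genome_id
  if (nrow(cds$genes) < 3L) {
    stop("genome ", genome_id, ": fewer than 3 genes pass the filters",
         call. = FALSE)
  }
  m <- cds$counts

  comp_gene <- gene_composition(cds, space,
                                synonymous_only = config$synonymous_only)
  comp_genome <- genome_composition(cds, space, genome_id = genome_id,
                                    synonymous_only = config$synonymous_only)
  table1 <- composition_percent_table(comp_genome)

  rscu_pooled <- rscu(colSums(m), space)
  rscu_mat <- t(vapply(seq_len(nrow(m)),
                       function(i) as.numeric(rscu(m[i, ], space)),
                       numeric(length(space$analysis_codons))))
  dimnames(rscu_mat) <- list(cds$genes$gene_id, space$analysis_codons)

  opt <- optimal_codons(cds, space, decile = config$decile,
                        delta_threshold = config$delta_threshold,
                        high_group = config$high_group,
                        rscu_scope = config$rscu_scope)
  ref_w <- reference_w_from_high_set(m[opt$high_group, , drop = FALSE],
                                     space, w_floor = config$w_floor)
  idx <- index_summary(cds, space, reference_w = ref_w,
                       optimal = if (length(opt$optimal_codons))
                         opt$optimal_codons else NULL,
                       decile = config$decile,
                       delta_threshold = config$delta_threshold)

  diag <- selection_diagnostics(cds, space,
                                synonymous_only = config$synonymous_only)
  ratios <- diag$enc_ratio[is.finite(diag$enc_ratio)]
  hist_df <- if (length(ratios)) enc_ratio_histogram(ratios) else NULL

  fit <- neutrality_fit(comp_gene$gc12, comp_gene$gc3, genome_id = genome_id,
                        orientation = config$neutrality_orientation)

  enc_ok <- idx$enc[is.finite(idx$enc)]
  table2 <- data.frame(
    genome_id = genome_id,
    mean_enc = round(mean(enc_ok), 2),
    n_enc_strong = sum(enc_ok < config$enc_strong_threshold),
    n_enc_weak = sum(enc_ok >= config$enc_strong_threshold & enc_ok <= 61),
    n_enc_undefined = sum(!is.finite(idx$enc)),
    stringsAsFactors = FALSE
  )

  ca <- correspondence_analysis(rscu_mat)
  corr_vars <- data.frame(
    gene_id = idx$gene_id,
    gc1 = comp_gene$gc1, gc2 = comp_gene$gc2, gc3 = comp_gene$gc3,
    gc3s = comp_gene$gc3s, gc_all = comp_gene$gc_all,
    cai = idx$cai, cbi = idx$cbi, enc = idx$enc, l_aa = idx$l_aa,
    stringsAsFactors = FALSE
  )
  correlations <- if (ca$n_axes >= 1L) {
    axis1_correlations(ca, corr_vars, method = config$cor_method)
  } else NULL

  structure(
    list(genome_id = genome_id, config = config, cds = cds,
         filter_report = cds$report,
         gene_composition = comp_gene, genome_composition = comp_genome,
         table1_row = table1, rscu_pooled = rscu_pooled,
         rscu_matrix = rscu_mat,
         high_frequency_codons = high_frequency_codons(rscu_pooled),
         optimal = opt, indices = idx, diagnostics = diag,
         enc_ratio_hist = hist_df, neutrality = fit, table2_row = table2,
         ca = ca, correlations = correlations),
    class = "genome_result"
  )
}

#' @export
print.genome_result <- function(x, ...) {
  cat("<genome_result>", x$genome_id, "-", nrow(x$indices), "genes\n")
  cat(sprintf("  mean ENC %.2f (%d genes ENC < %g), %d optimal codons, %d HF codons\n",
              x$table2_row$mean_enc, x$table2_row$n_enc_strong,
              x$config$enc_strong_threshold,
              length(x$optimal$optimal_codons),
              length(x$high_frequency_codons)))
  cat(sprintf("  neutrality slope %.3f (mutation %.1f%% / selection %.1f%%)\n",
              x$neutrality$slope, x$neutrality$mutation_pct,
              x$neutrality$selection_pct))
  invisible(x)
}

#' Run the analysis across a cohort of genomes
#'
#' Per-genome bundles plus the cross-genome artifacts: the shared
#' high-frequency codon set (intersection across genomes), the base-ending
#' tally of that shared set, the genomes x 59 pooled-RSCU matrix (heat-map
#' input), and a summary of neutrality slopes. A failing genome is
#' recorded and the cohort continues.
#'
#' @param inputs Named list (or vector of paths) of per-genome inputs
#'   accepted by [run_genome()].
#' @param space A [build_codon_space()] object.
#' @param config A [cub_config()].
#' @return Object of class `cohort_result`: `genomes` (list of
#'   `genome_result`), `failures` (named character of error messages),
#'   `table1`, `table2`, `shared_high_frequency`, `shared_ending_tally`
#'   (named A/T/G/C counts), `rscu_matrix` (genomes x 59),
#'   `slope_summary` (min/max/mean), `neutrality` (per-genome rows).
#' @export
run_cohort <- function(inputs, space = build_codon_space(),
                       config = cub_config()) {
  if (length(inputs) < 2L) stop("need at least 2 genomes", call. = FALSE)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    nm <- vapply(seq_along(inputs), function(i) {
      x <- inputs[[i]]
      if (inherits(x, "synthetic_genome")) x$genome_id
      else if (is.character(x) && length(x) == 1L && file.exists(x))
        sub("\\.[^.]*$", "", basename(x))
      else sprintf("genome_%02d", i)
    }, character(1))
    names(inputs) <- make.unique(nm, sep = "_")
  }
  genomes <- list(); failures <- character()
  for (id in names(inputs)) {
    res <- tryCatch(run_genome(inputs[[id]], genome_id = id, space = space,
                               config = config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      genomes[[id]] <- res
    }
  }
  if (length(genomes) == 0L) stop("all genomes failed", call. = FALSE)

  table1 <- do.call(rbind, lapply(genomes, function(g) g$table1_row))
  table2 <- do.call(rbind, lapply(genomes, function(g) g$table2_row))
  rownames(table1) <- rownames(table2) <- NULL

  shared <- Reduce(intersect, lapply(genomes, function(g)
    g$high_frequency_codons))
  ending <- substr(shared, 3L, 3L)
  ending_tally <- vapply(c("A", "T", "G", "C"),
                         function(b) sum(ending == b), integer(1))

  rscu_mat <- t(vapply(genomes, function(g) as.numeric(g$rscu_pooled),
                       numeric(length(space$analysis_codons))))
  dimnames(rscu_mat) <- list(names(genomes), space$analysis_codons)

  neut <- do.call(rbind, lapply(genomes, function(g)
    neutrality_row(g$neutrality)))
  rownames(neut) <- NULL
  slopes <- neut$slope
  structure(
    list(genomes = genomes, failures = failures,
         table1 = table1, table2 = table2,
         shared_high_frequency = shared, shared_ending_tally = ending_tally,
         rscu_matrix = rscu_mat,
         slope_summary = c(min = min(slopes), max = max(slopes),
                           mean = mean(slopes)),
         neutrality = neut, config = config),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>", length(x$genomes), "genomes",
      if (length(x$failures)) paste0("(", length(x$failures), " failed)") else "",
      "\n")
  cat("  shared high-frequency codons:", length(x$shared_high_frequency), "\n")
  cat(sprintf("  neutrality slopes: min %.3f / mean %.3f / max %.3f\n",
              x$slope_summary[["min"]], x$slope_summary[["mean"]],
              x$slope_summary[["max"]]))
  invisible(x)
}

#' Write the result bundle of one genome to a directory
#'
#' Emits the TSV twins of every table and figure: filter report,
#' composition (Table-1 style), per-gene indices, pooled and per-gene
#' RSCU, the optimal-codon report with delta-RSCU, the per-gene
#' diagnostics, the ENC-ratio histogram, the neutrality fit, CA scores and
#' scree, the correlation report, plus PDF figures and a JSON run-metadata
#' file carrying the config fingerprint.
#'
#' @param result A `genome_result`.
#' @param dir Output directory (created if needed).
#' @param figures Write PDF figures as well?
#' @return `dir`, invisibly.
#' @export
write_genome_results <- function(result, dir, figures = TRUE) {
  stopifnot(inherits(result, "genome_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- function(f) file.path(dir, f)
  write_tsv_file(result$filter_report, pre("filter_report.tsv"))
  write_tsv_file(result$table1_row, pre("composition_table1.tsv"))
  write_tsv_file(result$gene_composition, pre("gene_composition.tsv"))
  write_tsv_file(result$indices, pre("gene_indices.tsv"))
  write_tsv_file(data.frame(codon = names(result$rscu_pooled),
                            rscu = as.numeric(result$rscu_pooled)),
                 pre("rscu_pooled.tsv"))
  write_tsv_file(cbind(gene_id = rownames(result$rscu_matrix),
                       as.data.frame(result$rscu_matrix)),
                 pre("rscu_per_gene.tsv"))
  opt <- result$optimal
  write_tsv_file(data.frame(codon = names(opt$delta_rscu),
                            rscu_high = as.numeric(opt$rscu_high),
                            rscu_low = as.numeric(opt$rscu_low),
                            delta_rscu = as.numeric(opt$delta_rscu),
                            optimal = names(opt$delta_rscu) %in%
                              opt$optimal_codons),
                 pre("optimal_codons.tsv"))
  write_tsv_file(result$diagnostics, pre("selection_diagnostics.tsv"))
  if (!is.null(result$enc_ratio_hist)) {
    write_tsv_file(result$enc_ratio_hist, pre("enc_ratio_histogram.tsv"))
  }
  write_tsv_file(neutrality_row(result$neutrality), pre("neutrality.tsv"))
  if (result$ca$n_axes > 0) {
    write_tsv_file(cbind(gene_id = rownames(result$ca$row_scores),
                         as.data.frame(result$ca$row_scores)),
                   pre("ca_row_scores.tsv"))
    write_tsv_file(cbind(codon = rownames(result$ca$col_scores),
                         as.data.frame(result$ca$col_scores)),
                   pre("ca_col_scores.tsv"))
    write_tsv_file(data.frame(axis = seq_len(result$ca$n_axes),
                              inertia_pct = result$ca$inertia_pct),
                   pre("ca_scree.tsv"))
  }
  if (!is.null(result$correlations)) {
    write_tsv_file(result$correlations, pre("axis1_correlations.tsv"))
  }
  meta <- list(genome_id = result$genome_id,
               package_version = as.character(utils::packageVersion("cubkit")),
               config_fingerprint = result$config$fingerprint,
               n_genes = nrow(result$indices))
  jsonlite::write_json(meta, pre("run_metadata.json"), auto_unbox = TRUE)
  if (figures) {
    save_plot_quiet(plot_enc_gc3s(result$diagnostics), pre("enc_plot.pdf"))
    save_plot_quiet(plot_pr2(result$diagnostics), pre("pr2_plot.pdf"))
    save_plot_quiet(plot_neutrality(result$gene_composition,
                                    result$neutrality),
                    pre("neutrality_plot.pdf"))
    if (!is.null(result$enc_ratio_hist)) {
      save_plot_quiet(plot_enc_ratio_hist(result$enc_ratio_hist),
                      pre("enc_ratio_histogram.pdf"))
    }
    if (result$ca$n_axes >= 2) {
      save_plot_quiet(plot_ca(result$ca), pre("ca_biplot.pdf"))
    }
  }
  invisible(dir)
}

#' Write cohort-level results to a directory
#'
#' @param cohort A `cohort_result`.
#' @param dir Output directory; per-genome bundles go to subdirectories.
#' @param per_genome Also write every per-genome bundle?
#' @param figures Write PDF figures?
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(cohort, dir, per_genome = TRUE,
                                 figures = TRUE) {
  stopifnot(inherits(cohort, "cohort_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(cohort$table1, file.path(dir, "cohort_composition_table1.tsv"))
  write_tsv_file(cohort$table2, file.path(dir, "cohort_enc_table2.tsv"))
  write_tsv_file(data.frame(codon = cohort$shared_high_frequency),
                 file.path(dir, "shared_high_frequency_codons.tsv"))
  write_tsv_file(data.frame(ending = names(cohort$shared_ending_tally),
                            n = as.integer(cohort$shared_ending_tally)),
                 file.path(dir, "shared_codon_endings.tsv"))
  write_tsv_file(cbind(genome_id = rownames(cohort$rscu_matrix),
                       as.data.frame(cohort$rscu_matrix)),
                 file.path(dir, "cohort_rscu_matrix.tsv"))
  write_tsv_file(cohort$neutrality, file.path(dir, "cohort_neutrality.tsv"))
  if (length(cohort$failures)) {
    write_tsv_file(data.frame(genome_id = names(cohort$failures),
                              error = unname(cohort$failures)),
                   file.path(dir, "failures.tsv"))
  }
  if (per_genome) {
    for (g in cohort$genomes) {
      write_genome_results(g, file.path(dir, g$genome_id), figures = figures)
    }
  }
  invisible(dir)
}
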