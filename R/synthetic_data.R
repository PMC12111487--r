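#' Specification for a synthetic CDS set
#'
#' Describes one synthetic "genome": a set of CDSs with controllable
#' third-position GC content, per-family codon-preference strength with a
#' planted preferred-codon set, a high-bias/low-bias gene mixture, and
#' co-variation of GC12 and GC3 across genes that plants a known
#' neutrality-regression slope. Defaults emulate a chloroplast-like gene
#' set: ~40 filtered CDSs of 300-1500 nt, AT-rich third positions
#' (GC3 target 0.08), GC12 around 0.33, a 20% high-bias gene class, and a
#' planted neutrality slope of 0.37.
#'
#' @param seed Integer RNG seed (generation is deterministic under a fixed
#'   seed).
#' @param genome_id Genome label.
#' @param n_genes Number of genes.
#' @param length_range Min/max CDS length in nt; minimum >= 300, values
#'   rounded to multiples of 3.
#' @param gc3_target Target synonymous third-position GC fraction.
#' @param bias_strength Softmax preference (log-scale) for the planted
#'   codon in high-bias genes; 0 disables selection entirely.
#' @param class_mixture Fraction of genes in the high-bias class.
#' @param planted_optimal Character vector, one preferred codon per family;
#'   `NULL` picks a default A/T-ending codon per family.
#' @param neutrality_slope Planted slope of GC3 on GC12 across genes; `NA`
#'   switches the co-variation off (every gene gets `gc3_target` and the
#'   base amino-acid frequencies).
#' @param gc12_mean,gc12_sd Across-gene distribution of the GC12 target.
#' @param gc3_noise_sd Residual noise on the per-gene GC3 target.
#' @param met_trp_rate Per-codon rate of Met and of Trp.
#' @param aa_frequencies Optional named base frequencies over the 18
#'   analysis families (default uniform).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, genome_id = "synth1", n_genes = 40L,
                           length_range = c(300L, 1500L), gc3_target = 0.08,
                           bias_strength = 2, class_mixture = 0.2,
                           planted_optimal = NULL, neutrality_slope = 0.37,
                           gc12_mean = 0.33, gc12_sd = 0.06,
                           gc3_noise_sd = 0.01, met_trp_rate = 0.02,
                           aa_frequencies = NULL) {
  stopifnot(n_genes >= 1, length(length_range) == 2L,
            length_range[1L] >= 300, length_range[2L] >= length_range[1L],
            gc3_target > 0, gc3_target < 1,
            bias_strength >= 0, class_mixture >= 0, class_mixture <= 1,
            met_trp_rate >= 0, met_trp_rate < 0.25)
  length_range <- as.integer(round(length_range / 3) * 3)
  structure(
    list(seed = seed, genome_id = genome_id, n_genes = as.integer(n_genes),
         length_range = length_range, gc3_target = gc3_target,
         bias_strength = bias_strength, class_mixture = class_mixture,
         planted_optimal = planted_optimal,
         neutrality_slope = neutrality_slope,
         gc12_mean = gc12_mean, gc12_sd = gc12_sd,
         gc3_noise_sd = gc3_noise_sd, met_trp_rate = met_trp_rate,
         aa_frequencies = aa_frequencies),
    class = "synthetic_spec"
  )
}

#' Default planted preferred-codon set: one A/T-ending codon per family
#'
#' @param space A [build_codon_space()] object.
#' @return Character vector of 18 codons (one per family, T-ending where
#'   available, else A-ending).
#' @export
default_planted_codons <- function(space = build_codon_space()) {
  vapply(space$families, function(cods) {
    t_end <- cods[endsWith(cods, "T")]
    if (length(t_end)) t_end[[1L]] else cods[endsWith(cods, "A")][[1L]]
  }, character(1), USE.NAMES = FALSE)
}

# third-position base weights under mutational GC pressure s
third_base_weights <- function(s) {
  c(A = (1 - s) / 2, T = (1 - s) / 2, C = s / 2, G = s / 2)
}

# within-family codon probabilities: softmax of planted preference on top
# of third-position GC pressure
family_codon_probs <- function(space, s, bias, planted) {
  w3 <- third_base_weights(s)
  lapply(space$families, function(cods) {
    w <- w3[substr(cods, 3L, 3L)] * exp(bias * (cods %in% planted))
    stats::setNames(w / sum(w), cods)
  })
}

codon_gc12 <- function(codon) {
  (substr(codon, 1L, 1L) %in% c("G", "C")) / 2 +
    (substr(codon, 2L, 2L) %in% c("G", "C")) / 2
}

# Expected all-codon GC3 of a gene given mutational pressure s: start ATG
# (third base G) and the uniform stop (TAG in 3) are fixed, Met/Trp both
# end in G, and each family contributes its renormalised third-position GC
# (Ile deviates from s because it lacks a G-ending codon).
expected_gc3_realized <- function(s, space, bias, planted, base_freq,
                                  gc12_target, met_trp_rate, n_sense) {
  fam_probs <- family_codon_probs(space, s, bias, planted)
  w <- if (is.na(gc12_target)) base_freq else
    tilt_aa_frequencies(base_freq, fam_probs, gc12_target, met_trp_rate)
  p_gc3_f <- vapply(fam_probs, function(p) {
    sum(p[substr(names(p), 3L, 3L) %in% c("G", "C")])
  }, numeric(1))
  m <- met_trp_rate
  sense <- (1 - 2 * m) * sum(w * p_gc3_f) + 2 * m   # ATG, TGG end in G
  (1 + 1 / 3 + n_sense * sense) / (n_sense + 2)
}

# Invert expected_gc3_realized: the mutational pressure s that makes the
# expected realized GC3 hit `target` for this gene.
solve_gc3_pressure <- function(target, space, bias, planted, base_freq,
                               gc12_target, met_trp_rate, n_sense) {
  f <- function(s) expected_gc3_realized(s, space, bias, planted, base_freq,
                                         gc12_target, met_trp_rate,
                                         n_sense) - target
  lo <- 1e-4; hi <- 1 - 1e-4
  if (f(lo) * f(hi) > 0) {
    stop("configuration error: gc3 target ", signif(target, 3),
         " unreachable for this gene (outside the feasible GC3 range)",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# Tilt the 18-family frequencies so the expected GC12 over sense codons
# hits `target`, given the per-family codon distributions.
tilt_aa_frequencies <- function(base_freq, fam_probs, target, met_trp_rate) {
  c_f <- vapply(fam_probs, function(p) {
    sum(p * vapply(names(p), codon_gc12, numeric(1)))
  }, numeric(1))
  m <- met_trp_rate
  fixed <- m * 0 + m * 0.5               # ATG contributes 0, TGG 0.5
  gc12_of <- function(t) {
    w <- base_freq * exp(t * c_f)
    w <- w / sum(w)
    (1 - 2 * m) * sum(w * c_f) + fixed
  }
  f <- function(t) gc12_of(t) - target
  if (f(-60) * f(60) > 0) {
    stop("configuration error: gc12 target ", signif(target, 3),
         " unreachable with the given amino-acid frequencies", call. = FALSE)
  }
  t <- stats::uniroot(f, c(-60, 60), tol = 1e-9)$root
  w <- base_freq * exp(t * c_f)
  w / sum(w)
}

#' Generate one synthetic CDS set
#'
#' Every gene is ATG + sampled sense codons + a uniformly sampled stop, so
#' the whole set passes the CDS quality filters by construction. Sense
#' codons are drawn family-first: amino acids from (possibly tilted)
#' family frequencies, then a codon within the family from a softmax
#' combining third-position GC pressure with the planted-codon preference
#' (active only in high-bias genes). When `neutrality_slope` is set, each
#' gene receives a GC12 target (via amino-acid tilting) and a GC3 target
#' `gc3_target + slope * (gc12 - gc12_mean) + noise`, planting a known
#' slope for the neutrality regression.
#'
#' @param spec A [synthetic_spec()].
#' @param space A [build_codon_space()] object.
#' @param fasta_path Optional path; when given the CDSs are also written
#'   as FASTA.
#' @return Object of class `synthetic_genome`: list with `genome_id`,
#'   `sequences` (named character), `ground_truth` (data frame: `gene_id`,
#'   `class`, `bias_strength`, `gc12_target`, `gc3_target`, `length_nt`),
#'   `planted_optimal`, `neutrality_slope`, `spec`.
#' @export
generate_genome <- function(spec, space = build_codon_space(),
                            fasta_path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  assert_codon_space(space)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  planted <- spec$planted_optimal %||%
    (if (spec$bias_strength > 0) default_planted_codons(space) else character())
  if (length(planted) && !all(planted %in% space$analysis_codons)) {
    stop("configuration error: planted codons outside the analysis set",
         call. = FALSE)
  }
  base_freq <- spec$aa_frequencies %||%
    stats::setNames(rep(1 / length(space$families), length(space$families)),
                    names(space$families))
  base_freq <- base_freq[names(space$families)] / sum(base_freq)
  m_rate <- spec$met_trp_rate
  slope_on <- !is.na(spec$neutrality_slope)

  n <- spec$n_genes
  len_choices <- seq(spec$length_range[1L], spec$length_range[2L], by = 3L)
  lengths <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  hi_class <- stats::runif(n) < spec$class_mixture

  gc12_t <- rep(NA_real_, n)
  gc3_t <- rep(spec$gc3_target, n)
  if (slope_on) {
    gc12_t <- clamp(stats::rnorm(n, spec$gc12_mean, spec$gc12_sd), 0.08, 0.92)
    gc3_t <- clamp(spec$gc3_target +
                     spec$neutrality_slope * (gc12_t - spec$gc12_mean) +
                     stats::rnorm(n, 0, spec$gc3_noise_sd), 0.06, 0.95)
  }

  seqs <- character(n)
  for (i in seq_len(n)) {
    b <- if (hi_class[i]) spec$bias_strength else 0
    n_sense <- lengths[i] / 3L - 2L
    # slope-on mode plants gc3 targets on the realized (all-codon) GC3
    # scale, so invert the expectation; slope-off mode reads gc3_target as
    # the mutational pressure itself
    s_i <- if (slope_on) {
      solve_gc3_pressure(gc3_t[i], space, b, planted, base_freq,
                         gc12_t[i], m_rate, n_sense)
    } else gc3_t[i]
    fam_probs <- family_codon_probs(space, s_i, b, planted)
    freq_i <- if (slope_on) {
      tilt_aa_frequencies(base_freq, fam_probs, gc12_t[i], m_rate)
    } else base_freq
    cats <- c(names(space$families), "M", "W")
    probs <- c((1 - 2 * m_rate) * freq_i, m_rate, m_rate)
    aa_seq <- sample(cats, n_sense, replace = TRUE, prob = probs)
    codon_seq <- character(n_sense)
    for (aa in unique(aa_seq)) {
      idx <- which(aa_seq == aa)
      codon_seq[idx] <- switch(aa,
        M = "ATG", W = "TGG",
        sample(names(fam_probs[[aa]]), length(idx), replace = TRUE,
               prob = fam_probs[[aa]]))
    }
    stop_codon <- sample(space$stop_codons, 1L)
    seqs[i] <- paste0("ATG", paste(codon_seq, collapse = ""), stop_codon)
  }
  gene_ids <- sprintf("%s_g%03d", spec$genome_id, seq_len(n))
  names(seqs) <- gene_ids

  truth <- data.frame(
    gene_id = gene_ids,
    class = ifelse(hi_class, "high_bias", "low_bias"),
    bias_strength = ifelse(hi_class, spec$bias_strength, 0),
    gc12_target = gc12_t, gc3_target = gc3_t,
    length_nt = lengths, stringsAsFactors = FALSE
  )
  out <- structure(
    list(genome_id = spec$genome_id, sequences = seqs, ground_truth = truth,
         planted_optimal = planted, neutrality_slope = spec$neutrality_slope,
         spec = spec),
    class = "synthetic_genome"
  )
  if (!is.null(fasta_path)) write_synthetic_fasta(out, fasta_path)
  out
}

write_synthetic_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$sequences)
  names(dss) <- names(genome$sequences)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", x$genome_id, "-", length(x$sequences), "CDSs,",
      sum(x$ground_truth$class == "high_bias"), "high-bias\n")
  invisible(x)
}

#' Generate a cohort of synthetic genomes
#'
#' @param specs List of [synthetic_spec()] objects with distinct genome
#'   ids.
#' @param dir Optional output directory: one FASTA per genome, a
#'   ground-truth manifest TSV, and the specs serialised as JSON.
#' @param space A [build_codon_space()] object.
#' @return List of class `synthetic_cohort`: `genomes` (list of
#'   `synthetic_genome`), `manifest` (data frame), `dir`.
#' @export
generate_cohort <- function(specs, dir = NULL, space = build_codon_space()) {
  stopifnot(length(specs) >= 1L)
  ids <- vapply(specs, function(s) s$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("configuration error: duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  genomes <- lapply(specs, generate_genome, space = space)
  names(genomes) <- ids
  manifest <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(
      genome_id = g$genome_id, n_genes = length(g$sequences),
      seed = g$spec$seed %||% NA_integer_,
      gc3_target = g$spec$gc3_target,
      neutrality_slope = g$spec$neutrality_slope,
      bias_strength = g$spec$bias_strength,
      class_mixture = g$spec$class_mixture,
      planted_optimal = paste(g$planted_optimal, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genomes) {
      write_synthetic_fasta(g, file.path(dir, paste0(g$genome_id, ".fasta")))
    }
    write_tsv_file(manifest, file.path(dir, "ground_truth_manifest.tsv"))
    jsonlite::write_json(lapply(genomes, function(g) unclass(g$spec)),
                         file.path(dir, "synthetic_specs.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  structure(list(genomes = genomes, manifest = manifest, dir = dir),
            class = "synthetic_cohort")
}
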