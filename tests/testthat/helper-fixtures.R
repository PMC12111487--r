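# Shared fixtures: everything is built in code at test time.

space <- build_codon_space()

# a valid CDS: ATG + n_codons repeats of `codon` (+ optional extras) + stop
make_cds <- function(codon = "AAA", n_codons = 99L, stop = "TAA",
                     extra = character()) {
  paste0("ATG", paste(rep(codon, n_codons), collapse = ""),
         paste(extra, collapse = ""), stop)
}

# random codon-count vector over the 59 analysis codons
random_counts <- function(seed, max_count = 20L) {
  set.seed(seed)
  cnt <- stats::setNames(sample(0:max_count, 59, replace = TRUE),
                         space$analysis_codons)
  if (sum(cnt) == 0) cnt[1L] <- 1L
  cnt
}

# counts with one fixed codon per family (the ENC = 20 construction)
one_codon_per_family_counts <- function(n_each = 10L) {
  cods <- vapply(space$families, `[`, character(1), 1L)
  stats::setNames(rep(n_each, length(cods)), cods)
}

# equal counts of all 59 analysis codons (the ENC = 61 construction)
uniform_counts <- function(n_each = 30L) {
  stats::setNames(rep(n_each, 59), space$analysis_codons)
}

# tiny GenBank record with forward, complement, join, complement(join) and
# partial CDS features
write_test_genbank <- function(path) {
  writeLines(c(
    "LOCUS       TESTREC                  120 bp    DNA     circular PLN 01-JAN-2024",
    "DEFINITION  synthetic test record.",
    "ACCESSION   TESTREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"synthetic\"",
    "     CDS             4..15",
    "                     /gene=\"fwd1\"",
    "                     /product=\"forward gene\"",
    "     CDS             complement(20..31)",
    "                     /gene=\"rev1\"",
    "     CDS             join(40..48,60..65)",
    "                     /gene=\"spliced1\"",
    "     CDS             complement(join(70..75,80..85))",
    "                     /gene=\"revspliced\"",
    "     CDS             <90..101",
    "                     /gene=\"part1\"",
    "ORIGIN",
    "        1 aaaatgaaat aaccttacat ggggcccatg aaaccctaag gggttttttc cccggggaaa",
    "       61 tttaaagggc ccaaatttgg gtttaaaccc gggtttaaac ccggtttaaa atttaaaggg",
    "//"), path)
  toupper(paste0("aaaatgaaataaccttacatggggcccatgaaaccctaaggggttttttccccggggaaa",
                 "tttaaagggcccaaatttgggtttaaacccgggtttaaacccggtttaaaatttaaaggg"))
}

# independent brute-force CA oracle: eigendecomposition of S^T S, row
# scores via D_r^{-1/2} S V (never calls the package implementation)
brute_force_ca <- function(m) {
  grand <- sum(m)
  P <- m / grand
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  eg <- eigen(t(S) %*% S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- lam > max(lam) * 1e-12
  lam <- lam[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  row_scores <- diag(1 / sqrt(r)) %*% S %*% V
  list(inertia = lam, inertia_pct = 100 * lam / sum(lam),
       row_scores = row_scores)
}
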