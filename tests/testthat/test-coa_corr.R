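test_that("CA matches a brute-force eigendecomposition oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rexp(48), nrow = 6, ncol = 8)
    ca <- correspondence_analysis(m)
    bf <- brute_force_ca(m)
    k <- min(ca$n_axes, length(bf$inertia))
    expect_equal(ca$inertia[1:k], bf$inertia[1:k], tolerance = 1e-8)
    expect_equal(ca$inertia_pct[1:k], bf$inertia_pct[1:k], tolerance = 1e-8)
    for (ax in 1:k) {   # scores agree up to the sign indeterminacy
      a <- ca$row_scores[, ax]; b <- bf$row_scores[, ax]
      expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
  }
})

test_that("CA cross-checks against an independent library implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  m <- matrix(rpois(60, 8) + 1, nrow = 10, ncol = 6)
  ca <- correspondence_analysis(m)
  mc <- MASS::corresp(m, nf = 2)
  expect_equal(ca$sv[1:2], mc$cor[1:2], tolerance = 1e-8)
  # principal row coordinates = standard scores scaled by singular values
  for (ax in 1:2) {
    a <- ca$row_scores[, ax]; b <- mc$rscore[, ax] * mc$cor[ax]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("degenerate matrices yield the documented axis structure", {
  m2 <- rbind(a = c(4, 1, 1), b = c(1, 1, 4))
  ca2 <- correspondence_analysis(m2)
  expect_identical(ca2$n_axes, 1L)
  expect_equal(ca2$inertia_pct, 100)

  same <- rbind(a = c(2, 3, 5), b = c(4, 6, 10), c = c(2, 3, 5))
  ca0 <- correspondence_analysis(same)   # proportional rows: zero inertia
  expect_identical(ca0$n_axes, 0L)
  expect_equal(ca0$total_inertia, 0)

  withzero <- cbind(rbind(a = c(4, 1), b = c(1, 4)), z = c(0, 0))
  caz <- correspondence_analysis(withzero)
  expect_identical(caz$dropped_columns, "z")
})

test_that("CA satisfies the chi-square identity, transitions and ordering", {
  set.seed(21)
  m <- matrix(rpois(80, 6) + 1, nrow = 8, ncol = 10,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:10)))
  ca <- correspondence_analysis(m)
  chi <- suppressWarnings(stats::chisq.test(m)$statistic)
  expect_equal(ca$total_inertia, unname(chi) / sum(m), tolerance = 1e-10)
  expect_equal(sum(ca$inertia_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(ca$inertia) <= 1e-12))          # ordered axes
  expect_lte(ca$n_axes, min(dim(m)) - 1)

  # transition formula: F = D_r^{-1} P G D^{-1}
  P <- m / sum(m)
  F_trans <- diag(1 / rowSums(P)) %*% P %*% ca$col_scores %*%
    diag(1 / ca$sv, ca$n_axes)
  expect_equal(unname(ca$row_scores), unname(F_trans), tolerance = 1e-8)

  # reordering rows leaves the inertia spectrum unchanged
  ca_r <- correspondence_analysis(m[sample(nrow(m)), ])
  expect_equal(ca_r$inertia_pct, ca$inertia_pct, tolerance = 1e-10)
})

test_that("Axis-1 correlations anchor the sign and flag constants", {
  set.seed(31)
  g <- generate_genome(synthetic_spec(seed = 31, n_genes = 25), space)
  cs <- filter_cds(unname(g$sequences), space, "ca")
  comp <- gene_composition(cs, space)
  rm <- t(apply(cs$counts, 1, function(cnt) as.numeric(rscu(cnt, space))))
  colnames(rm) <- space$analysis_codons
  ca <- correspondence_analysis(rm)
  vars <- data.frame(gene_id = comp$gene_id, gc1 = comp$gc1, gc2 = comp$gc2,
                     gc3 = comp$gc3, gc3s = comp$gc3s, const = 1)
  rep1 <- axis1_correlations(ca, vars, method = "pearson")
  # anchored: Axis1 vs gc3s is non-negative
  expect_gte(rep1$estimate[rep1$var_b == "gc3s"], 0)
  expect_true(rep1$undefined[rep1$var_b == "const"])
  expect_true(all(abs(rep1$estimate[!rep1$undefined]) <= 1))
  # inter-variable pairs present exactly once
  expect_identical(sum(rep1$var_a == "gc3" & rep1$var_b == "gc1"), 1L)

  # perfect correlation when Axis1 is the variable itself
  vars2 <- data.frame(gene_id = rownames(ca$row_scores),
                      ax = ca$row_scores[, 1], gc3s = comp$gc3s)
  rep2 <- axis1_correlations(ca, vars2, method = "pearson")
  expect_equal(abs(rep2$estimate[rep2$var_b == "ax"]), 1, tolerance = 1e-12)

  # reflecting the axis flips every Axis-1 coefficient together
  ca_f <- ca
  ca_f$row_scores[, 1] <- -ca_f$row_scores[, 1]
  rep3 <- axis1_correlations(ca_f, vars, method = "pearson", align_to = NULL)
  rep4 <- axis1_correlations(ca, vars, method = "pearson", align_to = NULL)
  ax_rows <- rep3$var_a == "Axis1" & !rep3$undefined
  expect_equal(rep3$estimate[ax_rows], -rep4$estimate[ax_rows],
               tolerance = 1e-12)
})
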