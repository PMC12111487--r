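test_that("the expected-ENC curve matches its analytic anchors and symmetry", {
  expect_equal(enc_expected(0), 31.0)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32.0)
  s <- seq(0, 1, by = 0.01)
  # symmetric about 0.5 once the linear +s term is removed
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s),
               tolerance = 1e-12)
  # continuity: steps at 0.001 resolution bounded by the maximal slope
  fine <- enc_expected(seq(0, 1, by = 0.001))
  expect_lt(max(abs(diff(fine))), 0.1)
  expect_error(enc_expected(1.2), "0, 1")
})

test_that("the ENC ratio and its histogram behave arithmetically", {
  expect_equal(enc_ratio(40, 36), 0.1)
  expect_equal(enc_ratio(55, 55), 0)
  expect_equal(enc_ratio(60.5, 30.25), 0.5)
  expect_error(enc_ratio(0, 10), "positive")

  h <- enc_ratio_histogram(c(0.12, 0.13, 0.44), bin_width = 0.1)
  expect_equal(h$count[h$lower == 0.1], 2)
  expect_equal(h$count[h$lower == 0.4], 1)
  expect_equal(h$count[h$lower == 0.2], 0)   # empty interior bin reported
  expect_equal(sum(h$count), 3)
})

test_that("PR2 coordinates centre unbiased usage and flag degenerate genes", {
  expect_equal(as.numeric(pr2_point(0.25, 0.25, 0.25, 0.25)), c(0.5, 0.5))
  pt <- pr2_point(0.6, 0.3, 0.08, 0.02)
  expect_equal(as.numeric(pt), c(0.2, 2 / 3))
  bad <- pr2_point(1, 0, 0, 0)
  expect_true(attr(bad, "undefined"))
  expect_true(all(is.na(bad)))
})

test_that("fourfold-family PR2 points concentrate at the centre with length", {
  dist_to_centre <- function(len, variant) {
    g <- generate_genome(
      synthetic_spec(seed = 99, n_genes = 20, bias_strength = 0,
                     class_mixture = 0, neutrality_slope = NA,
                     gc3_target = 0.5, length_range = c(len, len)), space)
    cs <- filter_cds(unname(g$sequences), space, "p")
    d <- selection_diagnostics(cs, space, pr2_variant = variant)
    mean(sqrt((d$pr2_x - 0.5)^2 + (d$pr2_y - 0.5)^2))
  }
  expect_lt(dist_to_centre(6000, "fourfold"), dist_to_centre(300, "fourfold"))
  expect_lt(dist_to_centre(6000, "fourfold"), 0.05)
  # over the full analysis set the code structure itself displaces the
  # centre (purine-ending two-fold families have no C3 to contribute)
  expect_gt(dist_to_centre(6000, "synonymous"), 0.05)
})

test_that("neutrality regression recovers degenerate regimes exactly", {
  gc12 <- c(0.2, 0.3, 0.4, 0.5)
  # identity line: pure mutation
  f1 <- neutrality_fit(gc12, gc12)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$mutation_pct, 100, tolerance = 1e-10)
  # constant GC3: pure selection
  f0 <- neutrality_fit(gc12, rep(0.25, 4))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$selection_pct, 100, tolerance = 1e-10)
  # decomposition always sums to 100
  set.seed(2)
  f <- neutrality_fit(runif(20, 0.2, 0.5), runif(20, 0.05, 0.3))
  expect_equal(f$mutation_pct + f$selection_pct, 100, tolerance = 1e-10)

  expect_error(neutrality_fit(c(0.3, 0.3), c(0.1, 0.2)), "insufficient")
  expect_error(neutrality_fit(rep(0.3, 5), runif(5)), "variance")
})

test_that("mutation-only genomes track the expectation curve", {
  # smaller sibling of the acceptance check: two GC3 settings
  for (s in c(0.2, 0.7)) {
    g <- generate_genome(
      synthetic_spec(seed = round(100 * s), n_genes = 25, bias_strength = 0,
                     class_mixture = 0, neutrality_slope = NA, gc3_target = s,
                     length_range = c(3600, 7200)), space)
    cs <- filter_cds(unname(g$sequences), space, "mc")
    e <- enc_per_gene(cs, space)
    gs <- mean(vapply(seq_len(nrow(cs$counts)),
                      function(i) gc3s(cs$counts[i, ], space), numeric(1)))
    expect_lt(abs(mean(e) - enc_expected(gs)), 1.5)
  }
})
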