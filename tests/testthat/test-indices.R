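test_that("RSCU matches direct evaluation and conserves family sums", {
  r <- rscu(c(TTT = 3, TTC = 1), space)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  expect_equal(unname(rscu(c(AAA = 2), space)[c("AAA", "AAG")]), c(2, 0))
  # equal counts everywhere -> all RSCU exactly 1
  expect_true(all(rscu(uniform_counts(5), space) == 1))

  for (seed in 1:40) {
    cnt <- random_counts(seed)
    r <- rscu(cnt, space)
    for (aa in names(space$families)) {
      cods <- space$families[[aa]]
      k <- length(cods)
      if (sum(cnt[cods]) > 0) {
        expect_equal(sum(r[cods]), k, tolerance = 1e-9)
      } else {
        expect_true(all(r[cods] == 0))
        expect_true(aa %in% attr(r, "zero_families"))
      }
    }
  }
})

test_that("RSCU agrees with an independent sequence-level implementation", {
  skip_if_not_installed("seqinr")
  set.seed(13)
  g <- generate_genome(synthetic_spec(seed = 13, n_genes = 5,
                                      length_range = c(600, 900)), space)
  for (s in g$sequences[1:3]) {
    body <- substr(s, 1, nchar(s) - 3)   # drop terminal stop, as the 59-set does
    ours <- rscu(codon_counts(body), space)
    oracle <- seqinr::uco(seqinr::s2c(tolower(body)), index = "rscu")
    names(oracle) <- toupper(names(oracle))
    shared <- names(ours)[!is.na(oracle[names(ours)])]
    # compare on families the oracle observed
    obs <- shared[ours[shared] > 0 | oracle[shared] > 0]
    expect_equal(unname(ours[obs]), unname(oracle[obs]), tolerance = 1e-9)
  }
})

test_that("ENC reaches its analytic limits and hand-computed homozygosity", {
  e20 <- enc(one_codon_per_family_counts(10), space)
  expect_identical(e20$enc_obs, 20)
  e61 <- enc(uniform_counts(30), space)
  expect_identical(e61$enc_obs, 61)
  expect_gt(e61$enc_raw, 61)   # cap applied

  # single four-fold family with counts (3,1): F = (4 * 0.625 - 1)/3 = 0.5
  ef <- enc(c(GGT = 3, GGC = 1), space)
  expect_equal(unname(ef$f_bar[["4"]]), 0.5)

  expect_error(enc(c(ATG = 10), space), "undefined")
})

test_that("ENC stays in [20, 61] and falls as codon preference concentrates", {
  for (seed in 1:30) {
    e <- enc(random_counts(seed, max_count = 8), space)$enc_obs
    expect_gte(e, 20); expect_lte(e, 61)
  }
  for (seed in c(5, 6)) {
    means <- vapply(c(0, 1, 2, 4), function(b) {
      g <- generate_genome(
        synthetic_spec(seed = seed, n_genes = 15, bias_strength = b,
                       class_mixture = 1, neutrality_slope = NA,
                       gc3_target = 0.5, length_range = c(900, 1800)), space)
      cs <- filter_cds(unname(g$sequences), space, "m")
      mean(enc_per_gene(cs, space))
    }, numeric(1))
    expect_false(is.unsorted(rev(means)))
  }
})

test_that("CAI is the geometric mean of w, order-invariant, and at most 1", {
  w <- stats::setNames(rep(1, 59), space$analysis_codons)
  expect_equal(cai(c(TTT = 4, AAA = 3), w, space), 1)

  w2 <- c(TTT = 1, TTC = 0.25)
  expect_equal(cai(c(TTT = 1, TTC = 1), w2, space), 0.5)  # sqrt(1 * 0.25)
  # permutation of codon order within the count vector changes nothing
  expect_equal(cai(c(TTC = 1, TTT = 1), w2, space),
               cai(c(TTT = 1, TTC = 1), w2, space))

  # with a fixed reference, genes concentrated on w = 1 codons are maximal
  ref <- reference_w_from_high_set(c(GAA = 9, GAG = 1, TTT = 5, TTC = 5), space)
  best <- cai(c(GAA = 10, TTT = 5), ref, space)
  for (other in list(c(GAG = 10, TTC = 5), c(GAA = 5, GAG = 5, TTT = 5),
                     c(GAG = 10, TTT = 5))) {
    expect_lte(cai(other, ref, space), best)
  }
  expect_lte(best, 1)
  expect_error(cai(c(TTT = 1), numeric(0), space), "configuration")
})

test_that("reference w rescales pooled RSCU by the family maximum", {
  w <- reference_w_from_high_set(c(GAA = 9, GAG = 1), space)
  expect_equal(unname(w[c("GAA", "GAG")]), c(1, 1 / 9))
  # uniform usage gives w = 1 everywhere
  w_u <- reference_w_from_high_set(uniform_counts(2), space)
  expect_true(all(w_u == 1))
  # a single-gene reference reproduces that gene's RSCU-derived w
  cnt <- random_counts(3)
  w1 <- reference_w_from_high_set(cnt, space)
  r <- rscu(cnt, space)
  for (aa in names(space$families)) {
    cods <- space$families[[aa]]
    if (max(r[cods]) > 0) {
      expect_equal(unname(w1[cods]), unname(pmax(r[cods] / max(r[cods]), 0.01)))
    }
  }
})

test_that("CBI hits its endpoints and its random-usage zero", {
  opt <- c("GAA")                      # one optimal codon in a two-fold family
  expect_equal(cbi(c(GAA = 10), opt, space), 1)
  expect_equal(cbi(c(GAA = 5, GAG = 5), opt, space), 0)
  expect_equal(cbi(c(GAG = 10), opt, space), -1)
  # avoiding optimal codons across several two-fold families
  opt2 <- c("GAA", "AAA", "CAA")
  expect_equal(cbi(c(GAG = 4, AAG = 6, CAG = 2), opt2, space), -1)
  expect_error(cbi(c(GAA = 1), character(0), space), "configuration")
})

test_that("high-frequency codons are the strict RSCU > 1 set", {
  expect_length(high_frequency_codons(rscu(uniform_counts(3), space)), 0)
  r <- rscu(one_codon_per_family_counts(4), space)
  expect_length(high_frequency_codons(r), 18)
})

test_that("the decile delta-RSCU rule recovers a planted optimal set", {
  g <- generate_genome(
    synthetic_spec(seed = 11, genome_id = "opt", n_genes = 44,
                   bias_strength = 6, class_mixture = 0.2,
                   neutrality_slope = NA, gc3_target = 0.5,
                   length_range = c(600, 1500)), space)
  cs <- filter_cds(unname(g$sequences), space, "opt")
  oc <- optimal_codons(cs, space)
  expect_identical(length(oc$high_group), 5L)          # ceil(0.1 * 44)
  expect_identical(length(oc$low_group), 5L)
  expect_setequal(oc$optimal_codons, g$planted_optimal)
  expect_true(all(oc$optimal_codons %in% oc$high_frequency_codons))
  expect_true(all(oc$rscu_high[oc$optimal_codons] > 1))
  expect_true(all(oc$delta_rscu[oc$optimal_codons] > 0.08))

  # identical genes: no contrast, empty optimal set
  m <- matrix(rep(random_counts(1), 12), nrow = 12, byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:12), names(random_counts(1))))
  oc0 <- optimal_codons(m, space)
  expect_true(all(abs(oc0$delta_rscu) < 1e-12))
  expect_length(oc0$optimal_codons, 0)

  expect_error(optimal_codons(m[1:5, ], space), "insufficient")
})
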