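test_that("GenBank CDS extraction honours strand, splicing and partial flags", {
  gb <- withr::local_tempfile(fileext = ".gb")
  full <- write_test_genbank(gb)
  raw <- extract_cds(gb, "TESTREC")

  expect_identical(nrow(raw), 5L)
  expect_identical(raw$sequence[raw$cds_id == "fwd1"], substr(full, 4, 15))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(raw$sequence[raw$cds_id == "rev1"], rc(substr(full, 20, 31)))
  expect_identical(raw$sequence[raw$cds_id == "spliced1"],
                   paste0(substr(full, 40, 48), substr(full, 60, 65)))
  expect_identical(raw$sequence[raw$cds_id == "revspliced"],
                   rc(paste0(substr(full, 70, 75), substr(full, 80, 85))))
  expect_identical(raw$partial, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("FASTA extraction returns one record per entry", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 first", "ATGAAATAA", ">g2", "ATGCCCTGA", ">g3", "ATGTTTTAG"),
             fa)
  raw <- extract_cds(fa, "FA")
  expect_identical(nrow(raw), 3L)
  expect_identical(raw$cds_id, c("g1", "g2", "g3"))
  expect_false(any(raw$partial))
  expect_error(extract_cds(withr::local_tempfile(fileext = ".txt")),
               "not found")
})

test_that("each filter rejection is tallied under exactly one reason", {
  clean1 <- make_cds("AAA", 99)                       # 303 nt
  clean2 <- make_cds("GAT", 120, stop = "TGA")
  clean3 <- make_cds("TTC", 99, stop = "TAG")
  bad <- data.frame(
    cds_id = c("part", "n3", "short", "noatg", "nostop", "instop", "ambig"),
    sequence = c(
      make_cds("AAA", 99),                            # fine but partial
      paste0(make_cds("AAA", 99), "A"),               # 304 nt
      "ATGAAATAA",                                    # 9 nt
      sub("^ATG", "CTG", make_cds("AAA", 99)),
      sub("TAA$", "AAA", make_cds("AAA", 99)),
      make_cds("AAA", 49, extra = c("TGA", rep("AAA", 49))),  # stop at codon 51
      make_cds("AAN", 99)
    ),
    partial = c(TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  raw <- rbind(
    data.frame(cds_id = c("c1", "c2", "c3"),
               sequence = c(clean1, clean2, clean3),
               partial = FALSE, stringsAsFactors = FALSE),
    bad
  )
  raw$genome_id <- "fx"
  res <- filter_cds(raw, space)

  expect_identical(res$report$n_raw, 10L)
  expect_identical(res$report$n_pass, 3L)
  for (reason in c("partial", "not_multiple_of_3", "short", "no_atg_start",
                   "no_stop_end", "internal_stop", "ambiguous_base")) {
    expect_identical(res$report[[reason]], 1L)
  }
  # conservation: passes plus rejections account for every input
  rej <- sum(unlist(res$report[c("partial", "not_multiple_of_3", "short",
                                 "no_atg_start", "no_stop_end",
                                 "internal_stop", "ambiguous_base")]))
  expect_identical(res$report$n_pass + rej, res$report$n_raw)
  expect_setequal(res$genes$gene_id, c("c1", "c2", "c3"))
})

test_that("precedence assigns multiply-faulty sequences their first failure", {
  # short AND no ATG start AND internal-stop-free: tallied short only
  res <- filter_cds(c("CCCTAA"), space)
  expect_identical(res$report$short, 1L)
  expect_identical(res$report$no_atg_start, 0L)
})

test_that("filtering is idempotent and keeps exactly one terminal stop", {
  set.seed(41)
  g <- generate_genome(synthetic_spec(seed = 41, n_genes = 12), space)
  r1 <- filter_cds(unname(g$sequences), space, "s")
  r2 <- filter_cds(r1$genes$sequence, space, "s")
  expect_identical(unname(r1$counts), unname(r2$counts))
  expect_identical(r2$report$n_pass, r2$report$n_raw)

  stop_totals <- rowSums(r1$counts[, space$stop_codons])
  expect_true(all(stop_totals == 1))
  # counts sum to length/3
  expect_identical(unname(rowSums(r1$counts)),
                   as.numeric(r1$genes$length_nt / 3))
})
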