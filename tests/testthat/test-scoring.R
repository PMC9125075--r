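# Elite-haplotype counting, group summaries and marker-to-haplotype calls.

sv <- read_haplotype_survey()
em <- elite_map()

test_that("elite counts for benchmark accessions match the published survey", {
  sc <- score_panel(sv, em)
  counts <- stats::setNames(sc$elite_count, sc$accession)
  expect_equal(counts[["IR64"]], 10)
  expect_equal(counts[["R527"]], 10)
  expect_equal(counts[["YX1"]], 10)
  expect_equal(counts[["D62"]], 9)
  expect_equal(counts[["N22"]], 4)
  expect_equal(counts[["NIP"]], 0)
  gj_tmp <- sv$info$accession[sv$info$subpop == "GJ-tmp"]
  expect_length(gj_tmp, 6)
  expect_true(all(counts[gj_tmp] == 0))
})

test_that("n.d. never counts as elite and unknown genes error", {
  calls <- c(SBM1 = "HapB", OsNR2 = "n.d.", DNR1 = "HapA")
  expect_equal(count_elite(calls, em), 1)
  expect_error(count_elite(c(NOGENE = "HapB"), em), "absent")
})

test_that("counting is monotone in elite calls", {
  base <- stats::setNames(rep("HapA", 14), names(em))
  for (g in names(em)) {
    bumped <- base
    bumped[[g]] <- em[[g]][1]
    expect_equal(count_elite(bumped, em), count_elite(base, em) + 1)
  }
})

test_that("the SBM1 HapD toggle widens the elite map", {
  em2 <- elite_map(include_sbm1_hapd = TRUE)
  expect_setequal(em2$SBM1, c("HapB", "HapD"))
  sc2 <- score_panel(sv, em2)
  sc1 <- score_panel(sv, em)
  expect_true(all(sc2$elite_count >= sc1$elite_count))
})

test_that("group summaries tally carriers and never divide by zero", {
  sm <- summarize_by_group(sv, em)
  xi_myb <- sm$per_gene[sm$per_gene$gene == "MYB61" & sm$per_gene$group == "XI", ]
  expect_equal(xi_myb$n, 25)
  expect_equal(xi_myb$elite_carriers, 24)   # all but the n.d. accession TM
  gj <- sm$per_group[sm$per_group$group == "GJ", ]
  expect_equal(gj$max, 0)
  # whole-panel carrier counts are the sum over groups
  for (g in c("DNR1", "TOND1", "ARE1")) {
    per <- sm$per_gene[sm$per_gene$gene == g, ]
    expect_equal(sum(per$elite_carriers),
                 sum(sv$calls[, g] %in% em[[g]]))
  }
  empty <- list(calls = sv$calls[0, , drop = FALSE],
                info = sv$info[0, ], bold = NULL)
  class(empty) <- "haplotype_survey"
  expect_silent(summarize_by_group(empty, em))
})

test_that("printed-count discrepancies are flagged, not corrected", {
  sc <- score_panel(sv, em)
  flagged <- sc$accession[sc$count_discrepant]
  expect_true("HZ" %in% flagged)
  expect_equal(sc$elite_count[sc$accession == "HZ"], 8)
  expect_equal(sc$printed_count[sc$accession == "HZ"], 7)
})

test_that("paired markers resolve haplotype classes jointly", {
  mk <- marker_table_fixture()
  sbm1 <- mk[c("SBM1 E3 S", "SBM1 5U ID")]   # CAPS targets B+D, Indel B
  expect_equal(
    genotype_to_haplotype(c("SBM1 E3 S" = "alt_class",
                            "SBM1 5U ID" = "alt_class"), sbm1), "HapB")
  expect_equal(
    genotype_to_haplotype(c("SBM1 E3 S" = "alt_class",
                            "SBM1 5U ID" = "ref_class"), sbm1), "HapD")
  expect_equal(
    genotype_to_haplotype(c("SBM1 E3 S" = "ref_class",
                            "SBM1 5U ID" = "ref_class"), sbm1), "non-elite")
  ngr5 <- mk[c("NGR5 5U ID", "NGR5 I6 S")]   # Indel B+C+D, PARMS B
  expect_equal(
    genotype_to_haplotype(c("NGR5 5U ID" = "alt_class",
                            "NGR5 I6 S" = "alt_class"), ngr5), "HapB")
  expect_equal(
    genotype_to_haplotype(c("NGR5 5U ID" = "alt_class",
                            "NGR5 I6 S" = "ref_class"), ngr5), "HapC/HapD")
  # all-null and conflicting calls give n.d.
  expect_equal(
    genotype_to_haplotype(c("SBM1 E3 S" = "null",
                            "SBM1 5U ID" = "null"), sbm1), "n.d.")
  conflicted <- genotype_to_haplotype(c("SBM1 E3 S" = "ref_class",
                                        "SBM1 5U ID" = "alt_class"), sbm1)
  expect_equal(as.character(conflicted), "n.d.")
  expect_true(isTRUE(attr(conflicted, "conflict")))
})

test_that("single-marker genes report target haplotype or non-elite", {
  mk <- marker_table_fixture()
  tc <- mk["TCP19 5U ID"]
  expect_equal(genotype_to_haplotype(c("TCP19 5U ID" = "alt_class"), tc),
               "HapB")
  expect_equal(genotype_to_haplotype(c("TCP19 5U ID" = "ref_class"), tc),
               "non-elite")
  expect_equal(genotype_to_haplotype(c("TCP19 5U ID" = "null"), tc), "n.d.")
})

test_that("external panel tables load for one-command re-scoring", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("accession", "subpop", names(em)), collapse = "\t"),
    paste(c("ACCX", "XI-1B", "HapB", "HapB", "HapA", "HapA", "HapB",
            rep("HapA", 8), "n.d."), collapse = "\t"),
    paste(c("ACCY", "GJ-tmp", rep("HapA", 14)), collapse = "\t")
  ), f)
  pt <- read_panel_table(f)
  expect_equal(nrow(pt$calls), 2)
  sc <- score_panel(pt, em)
  expect_equal(sc$elite_count[sc$accession == "ACCX"], 3)
  expect_equal(sc$elite_count[sc$accession == "ACCY"], 0)
  expect_equal(pt$info$group, c("XI", "GJ"))
})
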