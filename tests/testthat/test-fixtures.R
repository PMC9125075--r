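# The synthetic-panel generator and the transcribed data fixtures.

test_that("panel generation is deterministic under the seed", {
  a <- generate_panel(random_panel_spec(501, 5, 3))
  b <- generate_panel(random_panel_spec(501, 5, 3))
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth_variants, b$truth_variants)
  c <- generate_panel(random_panel_spec(502, 5, 3))
  expect_false(identical(a$panel, c$panel))
})

test_that("the reference accession carries no alt allele", {
  pn <- generate_panel(random_panel_spec(503, 6, 3))
  geno <- pn$truth_matrix$genotypes
  expect_true(all(geno[pn$spec$ref_accession, ] == "ref"))
  expect_identical(pn$panel[[pn$spec$ref_accession]], pn$ref_locus$seq)
})

test_that("a two-haplotype spec yields recoverable profiles end to end", {
  spec <- panel_spec(
    seed = 504, upstream = 1500, downstream = 800,
    exon_lengths = c(600, 500), intron_lengths = 400,
    profiles = list(
      HapA = list(),
      HapB = list(list(position = -700, vtype = "DEL", len = 12),
                  list(position = 350, vtype = "SNP"),
                  list(position = 1500, vtype = "INS", len = 8))
    ),
    assignment = c(NIP = "HapA", A1 = "HapB", A2 = "HapB",
                   A3 = "HapA", A4 = "HapB", A5 = "HapA")
  )
  pn <- generate_panel(spec)
  expect_length(pn$panel, 6)
  vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
  expect_setequal(vm$variants$id, pn$truth_variants$id)
  hs <- group_haplotypes(vm, elite_profile = pn$truth_haps$haplotypes$HapB$profile)
  expect_equal(hs$haplotypes$HapB$members, c("A1", "A2", "A4"))
})

test_that("overlapping planted variants are rejected by the spec", {
  expect_error(panel_spec(
    seed = 1, profiles = list(
      HapA = list(),
      HapB = list(list(position = 100, vtype = "DEL", len = 10),
                  list(position = 110, vtype = "SNP"))
    ),
    assignment = c(NIP = "HapA", X = "HapB")
  ), "closer than 20")
})

test_that("a dense printed SNP set plants at the stated positions", {
  pos <- c(-1806, -1754, -1738, -1691, -1314, -935, -878, -844, -795,
           511, 641, 654, 2275, 3330)
  spec <- panel_spec(
    seed = 505, upstream = 2000, downstream = 1000,
    exon_lengths = c(700, 800, 900), intron_lengths = c(500, 600),
    profiles = list(HapA = list(),
                    HapB = lapply(pos, function(p) {
                      list(position = p, vtype = "SNP")
                    })),
    assignment = c(NIP = "HapA", NNE = "HapB")
  )
  pn <- generate_panel(spec)
  expect_equal(nrow(pn$truth_variants), 14)
  expect_setequal(pn$truth_variants$position, pos)
  vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
  expect_setequal(vm$variants$position, pos)
})

test_that("the bundled survey matches its printed anchors", {
  sv <- read_haplotype_survey()
  expect_equal(nrow(sv$calls), 36)
  expect_equal(ncol(sv$calls), 14)
  expect_equal(unname(sv$calls["NIP", "NGR2"]), "HapC")
  expect_true(all(sv$calls["NIP", setdiff(colnames(sv$calls), "NGR2")] ==
                    "HapA"))
  expect_equal(sv$info$printed_count[sv$info$accession == "NIP"], 0)
  expect_equal(unname(sv$calls["N22", "SBM1"]), "HapB")
  expect_true(sv$bold["N22", "SBM1"])
  expect_equal(unname(sv$calls["N22", "DNR1"]), "n.d.")
})

test_that("the bundled marker set parses bit-exact and re-emits identically", {
  mk <- marker_table_fixture()
  expect_length(mk, 18)
  census <- table(vapply(mk, `[[`, "", "mtype"))
  expect_equal(as.integer(census[c("Indel", "CAPS", "dCAPS", "PARMS")]),
               c(12L, 3L, 1L, 2L))
  tc <- mk[["TCP19 5U ID"]]
  expect_equal(tc$expected$ref, 231)
  expect_equal(tc$expected$alt - tc$expected$ref, -29)
  are1 <- mk[["ARE1 5U S"]]
  expect_equal(are1$enzyme$name, "DdeI")
  expect_equal(are1$expected$ref, 320)
  expect_equal(are1$expected$alt, c(100, 210))
  expect_equal(are1$target_haplotypes, "HapC")
  # byte-identical re-emission of the transcription (comments aside)
  src <- system.file("extdata", "marker_table.tsv", package = "haplomark")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(mk, tmp)
  body <- readLines(src)
  body <- body[!startsWith(body, "#")]
  expect_identical(readLines(tmp), body)
})
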