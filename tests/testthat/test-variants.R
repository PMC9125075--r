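# ATG-relative coordinates, region annotation, and variant calling from
# alignments.

test_that("ATG-relative labelling has no zero and inverts exactly", {
  loc <- locus_sequence("a", "g", strrep("ACGT", 1500), 2000, 5000)
  expect_equal(label_position(2000, loc), 1)    # the A of ATG
  expect_equal(label_position(2001, loc), 2)
  expect_equal(label_position(1999, loc), -1)
  expect_equal(label_position(0, loc), -2000)
  expect_error(label_position(6000, loc), "range")
  expect_error(unlabel_position(0, loc), "zero")
  offs <- c(0:10, 1995:2005, 5990:5999)
  expect_equal(unlabel_position(label_position(offs, loc), loc), offs)
  # bijection over the whole locus
  all_pos <- label_position(0:5999, loc)
  expect_equal(sort(unique(all_pos)), setdiff(-2000:4000, 0))
})

test_that("gene regions annotate as 5U/E/I/3U in transcription order", {
  # six-intron model built so that +3326 falls in intron 6
  ex_len <- c(300, 200, 250, 300, 250, 200, 700)
  in_len <- c(150, 200, 250, 300, 250, 800)
  cur <- 1001; rows <- list()
  for (k in seq_along(ex_len)) {
    rows[[k]] <- c(cur, cur + ex_len[k] - 1)
    cur <- cur + ex_len[k] + if (k <= 6) in_len[k] else 0
  }
  ex <- do.call(rbind, rows)
  gm <- gene_model("g", "c", "+", atg_pos = 1001,
                   stop_end = ex[7, 2], exons = ex)
  # intron 6 spans ATG-relative (sum of first 6 exons+5 introns .. +intron6)
  i6_lo <- sum(ex_len[1:6]) + sum(in_len[1:5]) + 1
  expect_gte(3326, i6_lo)
  expect_lte(3326, i6_lo + in_len[6] - 1)
  expect_equal(annotate_region(3326, gm), "I6")
  expect_equal(annotate_region(-443, gm), "5U")
  expect_equal(annotate_region(-1041, gm), "5U")
  expect_equal(annotate_region(1, gm), "E1")
  expect_equal(annotate_region(ex_len[1] + 5, gm), "I1")
  genic_len <- sum(ex_len) + sum(in_len)
  expect_equal(annotate_region(genic_len + 10, gm), "3U")
  expect_error(annotate_region(0, gm), "zero")
})

test_that("identical sequences call no variants", {
  pn <- generate_panel(random_panel_spec(41, 4, 2))
  ref <- pn$ref_locus
  self <- align_to_reference(ref, ref)
  expect_equal(nrow(call_variants(self)), 0)
})

test_that("a planted 29-bp promoter deletion is called at its position", {
  spec <- panel_spec(
    seed = 77, upstream = 2500, downstream = 500,
    exon_lengths = c(400, 400), intron_lengths = 200,
    profiles = list(HapA = list(),
                    HapB = list(list(position = -2022, vtype = "DEL", len = 29))),
    assignment = c(NIP = "HapA", ELITE = "HapB")
  )
  pn <- generate_panel(spec)
  qry <- locus_sequence("ELITE", "synthgene", pn$panel[["ELITE"]],
                        pn$ref_locus$atg_offset, pn$ref_locus$stop_offset)
  v <- call_variants(align_to_reference(qry, pn$ref_locus), pn$model)
  expect_equal(nrow(v), 1)
  expect_equal(v$vtype, "DEL")
  expect_equal(v$position, -2022)
  expect_equal(v$size_delta, -29)
  expect_equal(v$region, "5U")
})

test_that("called variants equal the planted truth across random panels", {
  for (s in 101:108) {
    pn <- generate_panel(random_panel_spec(s, 5, 3))
    vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
    expect_identical(sort(vm$variants$id), sort(pn$truth_variants$id),
                     info = paste("seed", s))
    # genotype rows match the planted assignment
    expect_identical(
      vm$genotypes[, sort(colnames(vm$genotypes)), drop = FALSE],
      pn$truth_matrix$genotypes[rownames(vm$genotypes),
                                sort(colnames(vm$genotypes)), drop = FALSE]
    )
  }
})

test_that("indels are left-aligned in repeat tracts", {
  # deletion of one AC unit from an (AC)5 tract: leftmost representation
  ref <- locus_sequence("r", "g", paste0("GGTTG", strrep("AC", 5), "GTTGG"), 1, 18)
  qry <- locus_sequence("q", "g", paste0("GGTTG", strrep("AC", 4), "GTTGG"), 1, 16)
  v <- call_variants(align_to_reference(qry, ref))
  expect_equal(nrow(v), 1)
  expect_equal(v$vtype, "DEL")
  # first affected base is the first A of the tract (offset 5 -> position +5)
  expect_equal(v$position, 5)
})

test_that("adjacent deletion+insertion gap blocks merge into one SUB", {
  ref_seq <- "AAAACCCCTTTT"
  qry_seq <- "AAAAGGGGGGTTTT"
  aln <- structure(list(
    ref_aln = "AAAACCCC------TTTT",
    query_aln = "AAAA----GGGGGGTTTT",
    score = NA_real_,
    ref = locus_sequence("r", "g", ref_seq, 1, nchar(ref_seq) - 1),
    query = locus_sequence("q", "g", qry_seq, 1, nchar(qry_seq) - 1)
  ), class = "locus_alignment")
  v <- call_variants(aln)
  expect_equal(nrow(v), 1)
  expect_equal(v$vtype, "SUB")
  expect_equal(v$ref_allele, "CCCC")
  expect_equal(v$alt_allele, "GGGGGG")
  expect_equal(v$size_delta, 2)
  # first replaced base is 0-based offset 4; with the ATG at offset 1 that
  # labels as +4
  expect_equal(v$position, 4)
})

test_that("variant tables round-trip through TSV", {
  v <- rbind(variant(-2022, "DEL", strrep("A", 29), "-", "5U"),
             variant(125, "SNP", "C", "T", "E1"),
             variant(-1197, "INS", "-", "GATTACAGATTACAGATTAC", "5U"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, f, gene = "g1", accession = "acc1")
  back <- read_variant_table(f)
  expect_equal(back$position, v$position)
  expect_equal(back$vtype, v$vtype)
  expect_equal(back$ref_allele, v$ref_allele)
  expect_equal(back$alt_allele, v$alt_allele)
})
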