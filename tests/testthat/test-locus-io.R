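test_that("panel FASTA reading enforces unique ids and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">NIP", "ACGT", ">IR64", "ACGA"), f)
  p <- read_panel_fasta(f)
  expect_identical(p, c(NIP = "ACGT", IR64 = "ACGA"))

  writeLines(c(">NIP", "ACGT", ">NIP", "ACGA"), f)
  expect_error(read_panel_fasta(f), "duplicate")

  panel <- c(A1 = "ACGTACGTACGT", A2 = "TTTTACGTCCCC", A3 = "GGGGAAAATTTT")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_panel_fasta(panel, f2)
  expect_identical(read_panel_fasta(f2), panel)
})

test_that("locus extraction obeys the fixed-window arithmetic", {
  set.seed(11)
  genome <- rand_seq(10000)
  gm <- gene_model("g1", "chr1", "+", atg_pos = 3001, stop_end = 6000,
                   exons = rbind(c(2900, 4000), c(4500, 6100)))
  loc <- extract_locus(genome, gm, upstream = 2000, downstream = 1000)
  expect_equal(nchar(loc$seq), 6000)
  expect_equal(loc$atg_offset, 2000)
  expect_equal(loc$stop_offset, 2000 + 3000 - 1)
  # invariant: length = upstream + genic + downstream for arbitrary flanks
  loc2 <- extract_locus(genome, gm, upstream = 500, downstream = 250)
  expect_equal(nchar(loc2$seq), 500 + 3000 + 250)
})

test_that("minus-strand extraction mirrors the plus-strand case", {
  set.seed(12)
  genome <- rand_seq(9000)
  gm_plus <- gene_model("g1", "chr1", "+", 3001, 6000,
                        rbind(c(2950, 4000), c(4400, 6050)))
  loc_plus <- extract_locus(genome, gm_plus, 1500, 800)
  # the same gene annotated on the reverse-complemented contig
  n <- nchar(genome)
  rc_genome <- revcomp(genome)
  flip <- function(x) n - x + 1
  gm_minus <- gene_model("g1", "chr1", "-", flip(3001), flip(6000),
                         rbind(flip(c(4000, 2950)), flip(c(6050, 4400))))
  loc_minus <- extract_locus(rc_genome, gm_minus, 1500, 800)
  expect_identical(loc_minus$seq, loc_plus$seq)
  expect_identical(loc_minus$atg_offset, loc_plus$atg_offset)
})

test_that("flanks running off the contig error unless truncation is allowed", {
  set.seed(13)
  genome <- rand_seq(4000)
  gm <- gene_model("g1", "c", "+", 1001, 3000, rbind(c(900, 3100)))
  expect_error(extract_locus(genome, gm, upstream = 2000, downstream = 500),
               "5'")
  expect_warning(
    loc <- extract_locus(genome, gm, upstream = 2000, downstream = 500,
                         allow_truncation = TRUE),
    "truncated"
  )
  expect_equal(loc$atg_offset, 1000)  # only 1 kb of upstream available
})

test_that("gene models read from TSV and GFF3 agree", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tseq_id\tstrand\tatg_pos\tstop_end\texons",
               "gA\tchr7\t+\t1200\t2600\t1100-1500,1900-2700"), tsv)
  m1 <- read_gene_model(tsv)
  expect_s3_class(m1, "gene_model")
  expect_equal(m1$atg_pos, 1200)
  expect_equal(nrow(m1$exons), 2)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr7\tsrc\tgene\t1100\t2700\t.\t+\t.\tID=gA",
    "chr7\tsrc\texon\t1100\t1500\t.\t+\t.\tParent=gA.1",
    "chr7\tsrc\texon\t1900\t2700\t.\t+\t.\tParent=gA.1",
    "chr7\tsrc\tCDS\t1200\t1500\t.\t+\t0\tParent=gA.1",
    "chr7\tsrc\tCDS\t1900\t2600\t.\t+\t0\tParent=gA.1"
  ), gff)
  m2 <- read_gene_model(gff, "gA")
  expect_equal(m2$atg_pos, m1$atg_pos)
  expect_equal(m2$stop_end, m1$stop_end)
  expect_equal(m2$exons, m1$exons)
})

test_that("synthetic loci carry a canonical start and stop codon", {
  pn <- generate_panel(random_panel_spec(21, 4, 2))
  loc <- pn$ref_locus
  expect_identical(substr(loc$seq, loc$atg_offset + 1, loc$atg_offset + 3),
                   "ATG")
  stop_codon <- substr(loc$seq, loc$stop_offset - 1, loc$stop_offset + 1)
  expect_true(stop_codon %in% c("TAA", "TAG", "TGA"))
})

test_that("enzyme catalogs parse recognition sites and reject bad offsets", {
  cat <- read_enzyme_catalog()
  expect_true(all(c("BglI", "TaqI", "DdeI") %in% names(cat$entries)))
  taq <- catalog_enzyme(cat, "TaqI")
  expect_equal(taq$recognition, "TCGA")
  expect_equal(taq$cut_offset, 1)
  dde <- catalog_enzyme(cat, "DdeI")
  expect_equal(dde$recognition, "CTNAG")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_offset", "XxxI\tACGT\t9"), bad)
  expect_error(read_enzyme_catalog(bad), "offset")
})
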