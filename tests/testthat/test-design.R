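# The design cascade: target selection, the four stages, priority order,
# naming, and the size-encoding scheme.

taq_only <- local({
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_offset", "TaqI\tTCGA\t1"), f)
  read_enzyme_catalog(f)
})

# a locus with clean random background (no TaqI sites) and a planted
# segment centred at ATG-relative position `pos`
toy_locus <- function(seed, planted, pos, n = 1400, atg_off = 700) {
  set.seed(seed)
  bg <- rand_seq(n)
  bg <- gsub("TCGA", "TCGG", bg, fixed = TRUE)
  while (grepl("TCGA", bg, fixed = TRUE)) bg <- gsub("TCGA", "TCGG", bg, fixed = TRUE)
  loc <- locus_sequence("REF", "toygene", bg, atg_off, n - 100)
  off <- unlabel_position(pos, loc)
  s <- loc$seq
  substr(s, off + 1 - (nchar(planted) %/% 2),
         off + nchar(planted) - (nchar(planted) %/% 2)) <- planted
  locus_sequence("REF", "toygene", s, atg_off, n - 100)
}

test_that("marker names compose gene, region and variation-type codes", {
  expect_equal(name_marker("NPF6.1", "5U", "Indel"), "NPF6.1 5U ID")
  expect_equal(name_marker("SBM1", "E3", "CAPS"), "SBM1 E3 S")
  expect_equal(name_marker("DNR1", "I4", "Indel"), "DNR1 I4 ID")
  expect_equal(name_marker("NGR5", "I6", "PARMS"), "NGR5 I6 S")
})

test_that("size encodings parse and format with side-of-slash semantics", {
  e <- parse_size_encoding("231 (-29)", "Indel")
  expect_equal(e$ref, 231); expect_equal(e$alt, 202); expect_equal(e$delta, -29)
  e <- parse_size_encoding("220 (+20)", "Indel")
  expect_equal(e$alt, 240)
  e <- parse_size_encoding("(249,24)/273", "CAPS")
  expect_equal(e$ref, c(249, 24)); expect_equal(e$alt, 273)
  e <- parse_size_encoding("320/(100,210)", "CAPS")
  expect_equal(e$ref, 320); expect_equal(e$alt, c(100, 210))
  # round trips
  for (s in c("231 (-29)", "220 (+20)", "1085 (-615)")) {
    expect_identical(format_size_encoding(parse_size_encoding(s, "Indel"),
                                          "Indel"), s)
  }
  for (s in c("(249,24)/273", "320/(100,210)", "380/(100,280)")) {
    expect_identical(format_size_encoding(parse_size_encoding(s, "CAPS"),
                                          "CAPS"), s)
  }
  expect_error(parse_size_encoding("220", "Indel"), "unparsable")
})

test_that("target selection keeps only variants private to the targets", {
  g <- matrix("ref", 6, 3,
              dimnames = list(c("NIP", "B1", "B2", "C1", "C2", "ND1"), NULL))
  g[c("B1", "B2"), 1] <- "alt"                 # HapB-private
  g[c("B1", "B2", "C1", "C2"), 2] <- "alt"     # shared B+C
  g[c("C1", "C2"), 3] <- "alt"                 # HapC-private
  ids <- c("-1197:INS:->GATTACAGATTACAGATTAC", "125:SNP:C>T", "900:SNP:G>A")
  vs <- rbind(variant(-1197, "INS", "-", "GATTACAGATTACAGATTAC"),
              variant(125, "SNP", "C", "T"),
              variant(900, "SNP", "G", "A"))
  vs$id <- ids
  vm <- variant_matrix(vs, g, "NIP")
  hs <- group_haplotypes(vm, elite_profile = ids[1:2], exclude = "ND1")
  got_b <- select_target_variants(hs, vm, "HapB")
  expect_setequal(got_b$id, ids[1])
  # a haplotype family sharing one variant: all three targets carry it
  got_bc <- select_target_variants(hs, vm, c("HapB", "HapC"))
  expect_setequal(got_bc$id, ids[2])
  expect_error(select_target_variants(hs, vm, "HapZ"), "unknown")
})

test_that("stage 1: an in-range indel yields an Indel marker", {
  pn <- generate_panel(panel_spec(
    seed = 301, upstream = 1200, downstream = 600,
    exon_lengths = c(500, 400), intron_lengths = 250,
    profiles = list(HapA = list(),
                    HapB = list(list(position = -300, vtype = "INS", len = 20),
                                list(position = 410, vtype = "SNP"))),
    assignment = c(NIP = "HapA", E1 = "HapB", E2 = "HapB")
  ))
  vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
  hs <- group_haplotypes(vm, elite_profile = pn$truth_haps$haplotypes$HapB$profile)
  cand <- select_target_variants(hs, vm, "HapB")
  m <- design_cascade(cand, pn$ref_locus, enzymes = taq_only,
                      gene_label = "SYN", model = pn$model,
                      avoid_variants = vm$variants)
  expect_s3_class(m, "marker_assay")
  expect_equal(m$mtype, "Indel")
  expect_equal(m$stage, "Indel")
  expect_gte(m$expected$ref, 100); expect_lte(m$expected$ref, 300)
  expect_equal(m$expected$alt - m$expected$ref, 20)
  expect_match(m$name, "^SYN 5U ID$")
})

test_that("stage 2: a site-creating SNP yields a CAPS marker", {
  # ref TCAA -> alt TCGA at the planted position
  loc <- toy_locus(302, "ATTCAAT", 250)
  off <- unlabel_position(250, loc)          # 0-based centre of the plant
  expect_equal(substr(loc$seq, off, off + 3), "TCAA")
  snp <- variant(label_position(off + 1, loc), "SNP", "A", "G")
  snp$has_n <- FALSE; snp$id <- variant_id(snp)
  m <- design_cascade(snp, loc, enzymes = taq_only, gene_label = "TOY")
  expect_s3_class(m, "marker_assay")
  expect_equal(m$stage, "CAPS")
  expect_equal(m$enzyme$name, "TaqI")
  amp <- sum(m$expected$ref)
  expect_gte(amp, 100); expect_lte(amp, 500)
  # exactly one class cuts
  expect_true(xor(length(m$expected$ref) > 1, length(m$expected$alt) > 1))
})

test_that("stage 3: an engineered mismatch yields a dCAPS marker", {
  # template TAGA around the SNP: no natural site for either allele, but
  # A->c two bases 5' of the SNP completes TCGA for the reference allele
  loc <- toy_locus(303, "GTTAGAGT", 300)
  off0 <- unlabel_position(300, loc)
  # planted TAGA spans 1-based (off0-1 .. off0+2); its final A is the SNP
  expect_equal(substr(loc$seq, off0 - 1, off0 + 2), "TAGA")
  snp <- variant(label_position(off0 + 1, loc), "SNP", "A", "C")
  snp$has_n <- FALSE; snp$id <- variant_id(snp)
  m <- design_cascade(snp, loc, enzymes = taq_only, gene_label = "TOY")
  expect_s3_class(m, "marker_assay")
  expect_equal(m$stage, "dCAPS")
  f <- m$primers$F
  low <- which(strsplit(f, "")[[1]] %in% letters)
  expect_equal(length(low), 1)
  # engineered base within positions 2..6 from the 3' end, never terminal
  expect_gte(nchar(f) - low[1] + 1, 2)
  expect_lte(nchar(f) - low[1] + 1, 6)
  # primer differs from the reference template at exactly the marked base
  off0 <- regexpr(gsub("[a-z]", ".", f), loc$seq)  # locate by fixed bases
  expect_gte(off0, 1)
  tmpl <- substr(loc$seq, off0, off0 + nchar(f) - 1)
  diffs <- which(strsplit(toupper(f), "")[[1]] != strsplit(tmpl, "")[[1]])
  expect_equal(diffs, low)
})

test_that("stage 4: with no engineerable site the cascade reaches PARMS", {
  loc <- toy_locus(306, "GTTTATTTG", 350)
  off <- unlabel_position(350, loc)
  # the planted segment centres the SNP base (A) at 1-based off+1
  expect_equal(substr(loc$seq, off - 3, off + 5), "GTTTATTTG")
  snp <- variant(350, "SNP", "A", "T")
  snp$has_n <- FALSE; snp$id <- variant_id(snp)
  m <- design_cascade(snp, loc, enzymes = taq_only, gene_label = "TOY")
  expect_s3_class(m, "marker_assay")
  expect_equal(m$stage, "PARMS")
  cfg <- design_config()
  expect_true(startsWith(m$primers$FC, cfg$tail_fam))
  expect_true(startsWith(m$primers$FT, cfg$tail_hex))
  core_fc <- substr(m$primers$FC, nchar(cfg$tail_fam) + 1, nchar(m$primers$FC))
  core_ft <- substr(m$primers$FT, nchar(cfg$tail_hex) + 1, nchar(m$primers$FT))
  expect_identical(substr(core_fc, 1, nchar(core_fc) - 1),
                   substr(core_ft, 1, nchar(core_ft) - 1))
  expect_false(substr(core_fc, nchar(core_fc), nchar(core_fc)) ==
                 substr(core_ft, nchar(core_ft), nchar(core_ft)))
})

test_that("dCAPS search agrees with brute-force enumeration on a toy context", {
  set.seed(305)
  # SNP at position 41 of a small context, TaqI only; with the ATG offset at
  # 0 the ATG-relative position equals the 1-based context position
  ctx <- rand_seq(120)
  ctx <- gsub("TCGA", "TCGG", ctx, fixed = TRUE)
  substr(ctx, 37, 41) <- "GTAGA"          # SNP = final A at 41
  loc <- locus_sequence("REF", "toy", ctx, 0, 118)
  hits <- oracle_dcaps_search(ctx, 41, "A", "C", taq_only$entries)
  expect_gt(nrow(hits), 0)
  # the package's search (primer constraints relaxed so the toy fits)
  cfg <- design_config(primer_len = c(18, 24), tm_range = c(0, 100),
                       gc_range = c(0, 1), dcaps_amplicon = c(30, 90))
  snp <- variant(41, "SNP", "A", "C")
  snp$has_n <- FALSE; snp$id <- variant_id(snp)
  m <- design_dcaps(snp, loc, cfg, taq_only)
  skip_if(inherits(m, "design_failure"), "no reverse primer fits the toy")
  f <- m$primers$F
  low <- which(strsplit(f, "")[[1]] %in% letters)
  e_end <- regexpr(gsub("[a-z]", ".", f), loc$seq) + nchar(f) - 1
  found <- hits[hits$end == e_end &
                  hits$mm_offset == (nchar(f) - low[1] + 1) &
                  hits$base == toupper(substr(f, low[1], low[1])), ]
  expect_equal(nrow(found), 1)
})

test_that("structural variants are emitted only via the override", {
  pn <- generate_panel(panel_spec(
    seed = 306, upstream = 1200, downstream = 600,
    exon_lengths = c(600, 500), intron_lengths = 300,
    profiles = list(HapA = list(),
                    HapB = list(list(position = 200, vtype = "DEL", len = 200))),
    assignment = c(NIP = "HapA", E1 = "HapB")
  ))
  vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
  cand <- vm$variants
  cfg_off <- design_config(allow_structural_override = FALSE)
  out <- design_cascade(cand, pn$ref_locus, cfg_off, taq_only,
                        gene_label = "SYN", model = pn$model)
  expect_s3_class(out, "design_failure")
  expect_warning(
    m <- design_cascade(cand, pn$ref_locus, design_config(), taq_only,
                        gene_label = "SYN", model = pn$model),
    "structural"
  )
  expect_s3_class(m, "marker_assay")
  expect_equal(m$expected$ref - m$expected$alt, 200)
  expect_match(m$stage, "structural")
})

test_that("sub-threshold indels fail the Indel stage", {
  v <- variant(100, "DEL", "ACT", "-")
  v$has_n <- FALSE; v$id <- variant_id(v)
  loc <- toy_locus(307, "AAAA", 100)
  out <- design_indel(v, loc, design_config(allow_structural_override = FALSE))
  expect_s3_class(out, "design_failure")
})

test_that("PARMS design requires the universal tails", {
  loc <- toy_locus(308, "CATGC", 200)
  snp <- variant(200, "SNP", substr(loc$seq, unlabel_position(200, loc) + 1,
                                    unlabel_position(200, loc) + 1), "T")
  cfg <- design_config(); cfg$tail_fam <- ""
  expect_error(design_parms(snp, loc, cfg), "tails")
})
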