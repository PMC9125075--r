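# The prioritized marker-design cascade: haplotype-diagnostic variants are
# turned into concrete assays in a fixed order of preference --
#   1. Indel marker   (indel of 5-30 bp; amplicon 100-300 bp, PAGE)
#   2. CAPS marker    (SNP creating/destroying a catalog enzyme site;
#                      amplicon 100-500 bp, agarose)
#   3. dCAPS marker   (engineered primer mismatch completes a site for one
#                      allele; amplicon 100-300 bp, PAGE)
#   4. PARMS marker   (allele-specific tailed forward primers, fluorescent
#                      read-out)
# -- with a structural-variant escape hatch for large indels that violate
# the size rules but are still typeable by amplicon size.

#' Construct a marker assay
#'
#' @param name Marker name (see [name_marker()]).
#' @param gene_id Gene identifier.
#' @param mtype `"Indel"`, `"CAPS"`, `"dCAPS"` or `"PARMS"`.
#' @param target_variant One-row variant data.frame ([variant()]).
#' @param target_haplotypes Haplotype names the assay selects for.
#' @param primers Named list of primer sequences: `F`/`R`, or `FC`/`FT`/`R`
#'   for PARMS.  Lowercase letters mark engineered dCAPS mismatches.
#' @param enzyme A [rest_enzyme()] for CAPS/dCAPS, else `NULL`.
#' @param expected Per-allele-class expected read-out: amplicon length
#'   (Indel), fragment-length vector (CAPS/dCAPS), or fluorophore name
#'   (PARMS), as `list(ref = , alt = )`.
#' @param size_encoding Compact printed form of `expected` (see
#'   [format_size_encoding()]); derived when missing.
#' @param stage Which cascade rule produced the assay.
#' @return An object of class `marker_assay`.
#' @export
marker_assay <- function(name, gene_id, mtype, target_variant,
                         target_haplotypes, primers, enzyme = NULL,
                         expected, size_encoding = NULL, stage = mtype) {
  mtype <- match.arg(mtype, c("Indel", "CAPS", "dCAPS", "PARMS"))
  if (mtype == "Indel" && !is.null(enzyme)) {
    stop("an Indel marker carries no restriction enzyme")
  }
  if (mtype %in% c("CAPS", "dCAPS")) {
    if (is.null(enzyme)) stop(mtype, " marker needs an enzyme")
    if (identical(sort(expected$ref), sort(expected$alt))) {
      stop(mtype, " expected fragment patterns must differ between classes")
    }
  }
  if (mtype == "dCAPS") {
    n_eng <- vapply(primers, function(p) {
      sum(strsplit(p, "")[[1]] %in% letters)
    }, 0L)
    if (sum(n_eng > 0L) != 1L) {
      stop("dCAPS marker must have exactly one primer with engineered mismatches")
    }
  }
  if (mtype == "PARMS") {
    if (!all(c("FC", "FT", "R") %in% names(primers))) {
      stop("PARMS marker needs primers FC, FT and R")
    }
  }
  if (is.null(size_encoding)) {
    size_encoding <- format_size_encoding(expected, mtype)
  }
  structure(
    list(name = name, gene_id = gene_id, mtype = mtype,
         target_variant = target_variant,
         target_haplotypes = target_haplotypes,
         primers = primers, enzyme = enzyme, expected = expected,
         size_encoding = size_encoding, stage = stage),
    class = "marker_assay"
  )
}

#' @export
print.marker_assay <- function(x, ...) {
  cat(sprintf("<marker_assay> %s  [%s]  targets %s\n", x$name, x$mtype,
              paste(x$target_haplotypes, collapse = ", ")))
  for (role in names(x$primers)) {
    cat(sprintf("  %-2s %s\n", role, x$primers[[role]]))
  }
  if (!is.null(x$enzyme)) cat("  enzyme:", x$enzyme$name, "\n")
  if (nzchar(x$size_encoding %||% "")) cat("  read-out:", x$size_encoding, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Name a marker
#'
#' The naming scheme is gene label + region code + variation-type code:
#' `ID` for an indel target, `S` for a SNP target (CAPS, dCAPS and PARMS
#' alike); regions render as `5U`, `E<k>`, `I<k>`, `3U`.
#'
#' @param gene_label Short gene label (e.g. `"NPF6.1"`).
#' @param region Region tag from [annotate_region()].
#' @param mtype Marker type.
#' @return Marker name string, e.g. `"NPF6.1 5U ID"`.
#' @export
name_marker <- function(gene_label, region, mtype) {
  code <- if (mtype == "Indel") "ID" else "S"
  paste(gene_label, region, code)
}

#' Parse and format the compact read-out encoding
#'
#' Indel markers print `"<ref> (<sign><delta>)"`: the reference-class
#' amplicon size with the elite-allele size change in brackets.  CAPS and
#' dCAPS markers print `"<ref>/<alt>"` where each side is either an uncut
#' amplicon size or a bracketed fragment list `"(a,b)"`; the side before the
#' slash is the reference class.
#'
#' @param s Encoding string.
#' @param mtype Marker type.
#' @return `parse_size_encoding`: a list `(ref, alt)` of numeric vectors
#'   (plus `delta` for Indel).  `format_size_encoding`: the string.
#' @examples
#' parse_size_encoding("231 (-29)", "Indel")
#' parse_size_encoding("(249,24)/273", "CAPS")
#' @export
parse_size_encoding <- function(s, mtype) {
  s <- trimws(s)
  if (mtype %in% c("Indel")) {
    m <- regexec("^(\\d+)\\s*\\(([+-]\\d+)\\)$", s)[[1]]
    parts <- regmatches(s, list(m))[[1]]
    if (length(parts) != 3L) stop("unparsable Indel size encoding: ", s)
    ref <- as.integer(parts[2]); delta <- as.integer(parts[3])
    return(list(ref = ref, alt = ref + delta, delta = delta))
  }
  if (mtype %in% c("CAPS", "dCAPS")) {
    halves <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("unparsable CAPS/dCAPS encoding: ", s)
    side <- function(h) {
      h <- trimws(h)
      if (grepl("^\\(", h)) {
        as.integer(strsplit(gsub("[()]", "", h), ",")[[1]])
      } else as.integer(h)
    }
    return(list(ref = side(halves[1]), alt = side(halves[2])))
  }
  stop("no size encoding defined for marker type ", mtype)
}

#' @rdname parse_size_encoding
#' @param expected A `list(ref, alt)` read-out (see [marker_assay()]).
#' @export
format_size_encoding <- function(expected, mtype) {
  if (mtype == "Indel") {
    delta <- expected$alt - expected$ref
    return(sprintf("%d (%+d)", expected$ref, delta))
  }
  if (mtype %in% c("CAPS", "dCAPS")) {
    side <- function(v) {
      if (length(v) == 1L) as.character(v)
      else paste0("(", paste(v, collapse = ","), ")")
    }
    return(paste0(side(expected$ref), "/", side(expected$alt)))
  }
  ""
}

#' Select variants diagnostic for the target haplotypes
#'
#' Returns the variants whose alt allele is carried by every member of the
#' target haplotype(s) and by no member of any other named haplotype
#' (n.d. accessions are ignored): the uniqueness rule for marker targets.
#'
#' @param haps A `haplotype_set`.
#' @param matrix The `variant_matrix` the haplotypes were derived from.
#' @param targets Haplotype names to select for (e.g. `"HapB"`, or several
#'   when one marker should tag a haplotype family).
#' @return Subset of `matrix$variants` (possibly zero rows).
#' @export
select_target_variants <- function(haps, matrix, targets) {
  stopifnot(inherits(haps, "haplotype_set"), inherits(matrix, "variant_matrix"))
  nm <- vapply(haps$haplotypes, `[[`, "", "name")
  if (!all(targets %in% nm)) {
    stop("unknown target haplotype(s): ",
         paste(setdiff(targets, nm), collapse = ", "))
  }
  in_target <- unlist(lapply(haps$haplotypes[nm %in% targets], `[[`, "members"))
  others <- unlist(lapply(haps$haplotypes[!nm %in% targets], `[[`, "members"))
  geno <- matrix$genotypes
  keep <- vapply(colnames(geno), function(id) {
    all(geno[in_target, id] == "alt") &&
      (!length(others) || all(geno[others, id] != "alt"))
  }, TRUE)
  matrix$variants[matrix$variants$id %in% colnames(geno)[keep], , drop = FALSE]
}

# 1-based locus interval occupied by a variant's reference allele
# (for insertions, the two bases flanking the insertion point).
variant_span <- function(v, ref_locus) {
  off <- unlabel_position(v$position, ref_locus)  # 0-based first affected base
  pos1 <- off + 1L
  ref_len <- if (identical(v$ref_allele, "-")) 0L else nchar(v$ref_allele)
  if (v$vtype == "INS") c(max(1L, pos1 - 1L), pos1)
  else c(pos1, pos1 + ref_len - 1L)
}

# Cut a design window around a span; returns list(seq, offset) where
# `offset` converts window coords to locus coords (locus = window + offset).
design_window <- function(ref_locus, span, reach) {
  lo <- max(1L, span[1] - reach)
  hi <- min(nchar(ref_locus$seq), span[2] + reach)
  list(seq = substr(ref_locus$seq, lo, hi), offset = lo - 1L,
       span = span - (lo - 1L))
}

# 1-based locus intervals of every variant except the target: amplicons must
# not span other segregating sites, or part of the panel would show shifted
# or differently cut products.
avoid_intervals <- function(avoid_variants, target, ref_locus) {
  if (is.null(avoid_variants) || !nrow(avoid_variants)) return(list())
  tid <- if (!is.null(target$id)) target$id else variant_id(target)
  ids <- if ("id" %in% names(avoid_variants)) avoid_variants$id else
    vapply(seq_len(nrow(avoid_variants)), function(i) {
      variant_id(avoid_variants[i, ])
    }, "")
  keep <- ids != tid
  lapply(which(keep), function(i) {
    variant_span(avoid_variants[i, ], ref_locus)
  })
}

overlaps_any <- function(lo, hi, intervals) {
  any(vapply(intervals, function(iv) lo <= iv[2] && hi >= iv[1], TRUE))
}

#' Design an Indel marker
#'
#' Primers flank the indel; the reference-class amplicon falls inside the
#' configured range, and the two allele classes differ by the indel size
#' (which must be resolvable on PAGE).  Indels outside the 5-30 bp size rule
#' are refused unless `cfg$allow_structural_override` is set, in which case a
#' structural-variant marker with relaxed amplicon bounds is emitted with a
#' warning.
#'
#' @param v One-row variant data.frame (INS/DEL/SUB).
#' @param ref_locus Reference [locus_sequence()].
#' @param cfg A [design_config()].
#' @param gene_label Gene label for the marker name.
#' @param model Optional [gene_model()] (for region annotation when the
#'   variant lacks one).
#' @param targets Target haplotype names recorded in the assay.
#' @param avoid_variants Optional data.frame of all segregating variants at
#'   the locus; the amplicon is placed so it spans none of them besides the
#'   target.
#' @return A [marker_assay()] or a `design_failure`.
#' @export
design_indel <- function(v, ref_locus, cfg = design_config(),
                         gene_label = ref_locus$gene_id, model = NULL,
                         targets = "HapB", avoid_variants = NULL) {
  if (!v$vtype %in% c("INS", "DEL", "SUB")) {
    return(design_failure("not an indel variant"))
  }
  delta <- v$size_delta
  if (abs(delta) < cfg$gel_resolution_page) {
    return(design_failure("size change below PAGE resolution"))
  }
  structural <- abs(delta) < cfg$indel_min || abs(delta) > cfg$indel_max
  if (structural && !cfg$allow_structural_override) {
    return(design_failure(sprintf(
      "indel size %d outside [%d, %d]", abs(delta), cfg$indel_min, cfg$indel_max)))
  }
  amp_range <- cfg$indel_amplicon
  if (structural) {
    ref_len <- if (identical(v$ref_allele, "-")) 0L else nchar(v$ref_allele)
    amp_range <- c(max(cfg$indel_amplicon[1], ref_len + 2L * cfg$primer_len[1]),
                   ref_len + 1000L)
  }
  span <- variant_span(v, ref_locus)
  win <- design_window(ref_locus, span, amp_range[2])
  avoid <- lapply(avoid_intervals(avoid_variants, v, ref_locus),
                  function(iv) iv - win$offset)
  pp <- design_primer_pair(win$seq, win$span, amp_range, cfg, avoid = avoid)
  if (is_failure(pp)) return(pp)
  if (structural) {
    warning("structural-variant override: indel of ", delta,
            " bp marketed outside the standard size rule")
  }
  region <- v$region
  if (is.na(region) && !is.null(model)) region <- annotate_region(v$position, model)
  marker_assay(
    name = name_marker(gene_label, region, "Indel"),
    gene_id = ref_locus$gene_id, mtype = "Indel", target_variant = v,
    target_haplotypes = targets,
    primers = list(F = pp$fwd, R = pp$rev),
    expected = list(ref = pp$amplicon, alt = pp$amplicon + delta),
    stage = if (structural) "Indel (structural override)" else "Indel"
  )
}

#' Design a CAPS marker
#'
#' Finds a catalog enzyme with a differential recognition site at the SNP
#' (either allele may carry the site), places primers so the amplicon lies
#' in the CAPS range, and computes the expected fragment patterns of both
#' allele classes by in-silico digestion.  Every fragment of the diagnostic
#' digest must be gel-visible (>= 20 bp) and the two patterns must be
#' distinguishable at agarose resolution.
#'
#' @inheritParams design_indel
#' @param enzymes An `enzyme_catalog`; catalog order is preference order.
#' @return A [marker_assay()] or a `design_failure`.
#' @export
design_caps <- function(v, ref_locus, cfg = design_config(),
                        enzymes = read_enzyme_catalog(),
                        gene_label = ref_locus$gene_id, model = NULL,
                        targets = "HapB", avoid_variants = NULL) {
  if (v$vtype != "SNP") return(design_failure("not a SNP"))
  if (isTRUE(v$has_n)) return(design_failure("allele contains N"))
  off <- unlabel_position(v$position, ref_locus)
  pos1 <- off + 1L
  n <- nchar(ref_locus$seq)
  avoid_loc <- avoid_intervals(avoid_variants, v, ref_locus)
  reasons <- character(0)
  for (enz in enzymes$entries) {
    w <- nchar(enz$recognition)
    lo <- max(1L, pos1 - w + 1L); hi <- min(n, pos1 + w - 1L)
    ctx_ref <- substr(ref_locus$seq, lo, hi)
    snp_at <- pos1 - lo + 1L
    ctx_alt <- ctx_ref
    substr(ctx_alt, snp_at, snp_at) <- v$alt_allele
    cls <- differential_site(ctx_ref, ctx_alt, enz)
    if (!cls %in% c("ref_only", "alt_only")) next
    span <- c(max(1L, pos1 - w + 1L), min(n, pos1 + w - 1L))
    win <- design_window(ref_locus, span, cfg$caps_amplicon[2])
    pp <- design_primer_pair(win$seq, win$span, cfg$caps_amplicon, cfg,
                             avoid = lapply(avoid_loc, function(iv) iv - win$offset))
    if (is_failure(pp)) { reasons <- c(reasons, paste0(enz$name, ": ", pp$reason)); next }
    amp_ref <- substr(win$seq, pp$fwd_start, pp$rev_end)
    amp_alt <- amp_ref
    snp_in_amp <- pos1 - win$offset - pp$fwd_start + 1L
    substr(amp_alt, snp_in_amp, snp_in_amp) <- v$alt_allele
    fr <- digest(amp_ref, enz); fa <- digest(amp_alt, enz)
    cut_frags <- if (cls == "ref_only") fr else fa
    if (min(cut_frags) < 20L) {
      reasons <- c(reasons, paste0(enz$name, ": digest fragment < 20 bp")); next
    }
    if (patterns_match(fr, fa, cfg$gel_resolution_agarose)) {
      reasons <- c(reasons, paste0(enz$name, ": patterns not resolvable")); next
    }
    region <- v$region
    if (is.na(region) && !is.null(model)) region <- annotate_region(v$position, model)
    return(marker_assay(
      name = name_marker(gene_label, region, "CAPS"),
      gene_id = ref_locus$gene_id, mtype = "CAPS", target_variant = v,
      target_haplotypes = targets,
      primers = list(F = pp$fwd, R = pp$rev), enzyme = enz,
      expected = list(ref = fr, alt = fa), stage = "CAPS"
    ))
  }
  design_failure(paste0("no differential enzyme site at the SNP",
                        if (length(reasons)) paste0(" (",
                          paste(reasons, collapse = "; "), ")") else ""))
}

#' Design a dCAPS marker
#'
#' Searches forward primers ending within `len(recognition) - 1` bases 5' of
#' the SNP, enumerating single-base substitutions at primer positions 2-6
#' from the 3' end (never the 3'-terminal base), such that primer plus
#' template context forms a recognition site overlapping the SNP for exactly
#' one allele.  The engineered primer is written with the substituted base
#' in lowercase.  Search order is deterministic: catalog order, primer end
#' closest to the SNP first, innermost mismatch position first, substitution
#' bases in alphabetical order, shortest primer first.
#'
#' @inheritParams design_caps
#' @return A [marker_assay()] or a `design_failure`.
#' @export
design_dcaps <- function(v, ref_locus, cfg = design_config(),
                         enzymes = read_enzyme_catalog(),
                         gene_label = ref_locus$gene_id, model = NULL,
                         targets = "HapB", avoid_variants = NULL) {
  if (v$vtype != "SNP") return(design_failure("not a SNP"))
  if (isTRUE(v$has_n)) return(design_failure("allele contains N"))
  off <- unlabel_position(v$position, ref_locus)
  pos1 <- off + 1L
  n <- nchar(ref_locus$seq)
  avoid_loc <- avoid_intervals(avoid_variants, v, ref_locus)
  for (enz in enzymes$entries) {
    w <- nchar(enz$recognition)
    if (pos1 - 1L < pos1 - w + 1L) next
    for (e in (pos1 - 1L):(pos1 - w + 1L)) {
      if (e < cfg$primer_len[1]) next
      for (m in 2L:6L) {
        mm_pos <- e - m + 1L                  # locus coord of engineered base
        if (mm_pos < 1L) next
        tmpl_base <- substr(ref_locus$seq, mm_pos, mm_pos)
        for (b in setdiff(c("A", "C", "G", "T"), tmpl_base)) {
          # the engineered product context around the SNP does not depend on
          # primer length: test site formation first, thermodynamics after
          ctx_lo <- max(1L, mm_pos - w)
          ctx_hi <- min(n, pos1 + w)
          ctx <- substr(ref_locus$seq, ctx_lo, ctx_hi)
          substr(ctx, mm_pos - ctx_lo + 1L, mm_pos - ctx_lo + 1L) <- b
          ctx_of <- function(allele) {
            at <- pos1 - ctx_lo + 1L
            substr(ctx, at, at) <- allele
            ctx
          }
          snp0 <- pos1 - ctx_lo
          ref_hit <- site_overlaps(ctx_of(v$ref_allele), enz, snp0)
          alt_hit <- site_overlaps(ctx_of(v$alt_allele), enz, snp0)
          if (ref_hit == alt_hit) next
          cls <- if (ref_hit) "ref_only" else "alt_only"
          for (len in cfg$primer_len[1]:cfg$primer_len[2]) {
            s <- e - len + 1L
            if (s < 1L || mm_pos < s) next
            primer <- substr(ref_locus$seq, s, e)
            substr(primer, mm_pos - s + 1L, mm_pos - s + 1L) <- b
            if (!primer_ok(primer, cfg)) next
            asy <- finish_dcaps(v, ref_locus, cfg, enz, primer, s, e,
                                mm_pos, b, pos1, cls, gene_label, model,
                                targets, avoid_loc)
            if (!is_failure(asy)) return(asy)
          }
        }
      }
    }
  }
  design_failure("no engineered mismatch creates a differential site")
}

# Pick a reverse primer for a fixed dCAPS forward primer and assemble the
# assay; fails when no amplicon in range or patterns not resolvable.
finish_dcaps <- function(v, ref_locus, cfg, enz, primer, s, e, mm_pos, b,
                         pos1, cls, gene_label, model, targets,
                         avoid_loc = list()) {
  n <- nchar(ref_locus$seq)
  w <- nchar(enz$recognition)
  if (length(avoid_loc) && overlaps_any(s, e, avoid_loc)) {
    return(design_failure("primer region spans another variant"))
  }
  rv <- enumerate_primers(ref_locus$seq, cfg,
                          region = c(pos1 + w, min(n, s + cfg$dcaps_amplicon[2] - 1L)),
                          reverse = TRUE)
  if (!nrow(rv)) return(design_failure("no reverse primer"))
  rv$amplicon <- rv$end - s + 1L
  rv <- rv[rv$amplicon >= cfg$dcaps_amplicon[1] &
             rv$amplicon <= cfg$dcaps_amplicon[2], , drop = FALSE]
  if (length(avoid_loc) && nrow(rv)) {
    rv <- rv[!vapply(rv$end, function(re) overlaps_any(s, re, avoid_loc), TRUE),
             , drop = FALSE]
  }
  rv <- rv[order(rv$amplicon, -rv$tm), , drop = FALSE]
  for (i in seq_len(nrow(rv))) {
    if (primer_3p_clash(primer, rv$seq[i])) next
    amp_of <- function(allele) {
      a <- paste0(primer, substr(ref_locus$seq, e + 1L, rv$end[i]))
      at <- nchar(primer) + (pos1 - e)
      substr(a, at, at) <- allele
      a
    }
    fr <- digest(amp_of(v$ref_allele), enz)
    fa <- digest(amp_of(v$alt_allele), enz)
    if (patterns_match(fr, fa, cfg$gel_resolution_page)) next
    region <- v$region
    if (is.na(region) && !is.null(model)) region <- annotate_region(v$position, model)
    primer_marked <- primer
    substr(primer_marked, mm_pos - s + 1L, mm_pos - s + 1L) <- tolower(b)
    return(marker_assay(
      name = name_marker(gene_label, region, "dCAPS"),
      gene_id = ref_locus$gene_id, mtype = "dCAPS", target_variant = v,
      target_haplotypes = targets,
      primers = list(F = primer_marked, R = rv$seq[i]), enzyme = enz,
      expected = list(ref = fr, alt = fa), stage = "dCAPS"
    ))
  }
  design_failure("no resolvable reverse primer")
}

#' Design a PARMS marker
#'
#' Builds the penta-primer allele-specific assay: two tailed forward primers
#' that share a template-binding core, end on the SNP base (one per allele),
#' and carry the two universal fluorophore tails; plus one common reverse
#' primer.  By convention the FAM-tailed primer (`FC`) carries the reference
#' allele and the HEX-tailed primer (`FT`) the alternate allele.
#'
#' @inheritParams design_indel
#' @return A [marker_assay()] or a `design_failure`.
#' @export
design_parms <- function(v, ref_locus, cfg = design_config(),
                         gene_label = ref_locus$gene_id, model = NULL,
                         targets = "HapB", avoid_variants = NULL) {
  if (v$vtype != "SNP") return(design_failure("not a SNP"))
  if (isTRUE(v$has_n)) return(design_failure("allele contains N"))
  if (!nzchar(cfg$tail_fam) || !nzchar(cfg$tail_hex)) {
    stop("PARMS design requires both universal tails in the config")
  }
  off <- unlabel_position(v$position, ref_locus)
  pos1 <- off + 1L
  n <- nchar(ref_locus$seq)
  avoid_loc <- avoid_intervals(avoid_variants, v, ref_locus)
  core <- NULL
  for (len in cfg$primer_len[1]:cfg$primer_len[2]) {
    s <- pos1 - len + 1L
    if (s < 1L) next
    if (length(avoid_loc) && overlaps_any(s, pos1, avoid_loc)) next
    binding <- substr(ref_locus$seq, s, pos1)   # ends on the SNP (ref base)
    if (primer_ok(binding, cfg)) { core <- list(start = s, seq = binding); break }
  }
  if (is.null(core)) {
    return(design_failure("no feasible allele-specific core ending on the SNP"))
  }
  rv <- enumerate_primers(ref_locus$seq, cfg,
                          region = c(pos1 + 1L,
                                     min(n, core$start + cfg$parms_amplicon[2] - 1L)),
                          reverse = TRUE)
  if (nrow(rv)) {
    rv$amplicon <- rv$end - core$start + 1L
    rv <- rv[rv$amplicon >= cfg$parms_amplicon[1] &
               rv$amplicon <= cfg$parms_amplicon[2], , drop = FALSE]
    if (length(avoid_loc) && nrow(rv)) {
      rv <- rv[!vapply(rv$end, function(re) {
        overlaps_any(core$start, re, avoid_loc)
      }, TRUE), , drop = FALSE]
    }
    rv <- rv[order(rv$amplicon, -rv$tm), , drop = FALSE]
  }
  if (!nrow(rv)) return(design_failure("no feasible common reverse primer"))
  stem <- substr(core$seq, 1L, nchar(core$seq) - 1L)
  fc <- paste0(cfg$tail_fam, stem, v$ref_allele)
  ft <- paste0(cfg$tail_hex, stem, v$alt_allele)
  hit <- NULL
  for (i in seq_len(nrow(rv))) {
    if (primer_3p_clash(core$seq, rv$seq[i])) next
    hit <- rv[i, ]; break
  }
  if (is.null(hit)) return(design_failure("3'-end complementarity with reverse primer"))
  region <- v$region
  if (is.na(region) && !is.null(model)) region <- annotate_region(v$position, model)
  marker_assay(
    name = name_marker(gene_label, region, "PARMS"),
    gene_id = ref_locus$gene_id, mtype = "PARMS", target_variant = v,
    target_haplotypes = targets,
    primers = list(FC = fc, FT = ft, R = hit$seq),
    expected = list(ref = "FAM", alt = "HEX"), stage = "PARMS"
  )
}

#' Run the full design cascade
#'
#' Tries, in order: Indel markers over in-size-range indel candidates; CAPS
#' over SNP candidates; dCAPS over SNP candidates; PARMS over SNP
#' candidates; and finally the structural-variant override for indels
#' outside the size rule (when enabled).  The first success is returned,
#' with `$stage` recording which rule fired; if every stage fails, a
#' `design_failure` listing the per-stage reasons is returned.
#'
#' @param candidates Data.frame of diagnostic variants
#'   ([select_target_variants()]).
#' @inheritParams design_caps
#' @return A [marker_assay()] or a `design_failure`.
#' @export
design_cascade <- function(candidates, ref_locus, cfg = design_config(),
                           enzymes = read_enzyme_catalog(),
                           gene_label = ref_locus$gene_id, model = NULL,
                           targets = "HapB", avoid_variants = NULL) {
  if (!nrow(candidates)) return(design_failure("no candidate variants"))
  if ("has_n" %in% names(candidates)) {
    candidates <- candidates[!candidates$has_n, , drop = FALSE]
    if (!nrow(candidates)) return(design_failure("all candidates carry N alleles"))
  }
  # by default, at least the other candidates must stay out of the amplicon
  if (is.null(avoid_variants)) avoid_variants <- candidates
  fails <- character(0)
  is_indel <- candidates$vtype %in% c("INS", "DEL", "SUB")
  in_range <- abs(candidates$size_delta) >= cfg$indel_min &
    abs(candidates$size_delta) <= cfg$indel_max
  cfg_no_override <- cfg; cfg_no_override$allow_structural_override <- FALSE
  for (i in which(is_indel & in_range)) {
    asy <- design_indel(candidates[i, ], ref_locus, cfg_no_override,
                        gene_label, model, targets, avoid_variants)
    if (!is_failure(asy)) return(asy)
    fails <- c(fails, paste0("Indel @", candidates$position[i], ": ", asy$reason))
  }
  if (!any(is_indel & in_range)) fails <- c(fails, "Indel: no candidate in size range")
  snps <- which(candidates$vtype == "SNP")
  if (!length(snps)) {
    fails <- c(fails, "CAPS/dCAPS/PARMS: no SNP candidate")
  } else {
    for (i in snps) {
      asy <- design_caps(candidates[i, ], ref_locus, cfg, enzymes,
                         gene_label, model, targets, avoid_variants)
      if (!is_failure(asy)) return(asy)
      fails <- c(fails, paste0("CAPS @", candidates$position[i], ": ", asy$reason))
    }
    for (i in snps) {
      asy <- design_dcaps(candidates[i, ], ref_locus, cfg, enzymes,
                          gene_label, model, targets, avoid_variants)
      if (!is_failure(asy)) return(asy)
      fails <- c(fails, paste0("dCAPS @", candidates$position[i], ": ", asy$reason))
    }
    for (i in snps) {
      asy <- design_parms(candidates[i, ], ref_locus, cfg, gene_label,
                          model, targets, avoid_variants)
      if (!is_failure(asy)) return(asy)
      fails <- c(fails, paste0("PARMS @", candidates$position[i], ": ", asy$reason))
    }
  }
  if (cfg$allow_structural_override) {
    for (i in which(is_indel & !in_range)) {
      asy <- design_indel(candidates[i, ], ref_locus, cfg, gene_label,
                          model, targets, avoid_variants)
      if (!is_failure(asy)) return(asy)
      fails <- c(fails, paste0("structural @", candidates$position[i], ": ",
                               asy$reason))
    }
  }
  design_failure(paste0("no design possible: ", paste(fails, collapse = " | ")))
}

# Two gel patterns are indistinguishable when they have the same number of
# bands and each size pair differs by less than the resolution.
patterns_match <- function(a, b, resolution) {
  if (length(a) != length(b)) return(FALSE)
  all(abs(sort(a) - sort(b)) < resolution)
}
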