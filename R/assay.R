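# Virtual genotyping: in-silico PCR, digestion, gel-resolution band calls
# and PARMS fluorophore calls, and marker validation against a panel with
# known haplotype truth.
#
# Binding model (a deliberate simplification of duplex thermodynamics): a
# primer binds where its 3'-terminal base matches exactly and at most
# `binding_max_mismatch` of its 3'-most `binding_anchor` bases mismatch.
# 5' overhangs beyond the anchor (universal PARMS tails) dangle without
# penalty, and engineered dCAPS mismatches still bind; a 3'-terminal
# mismatch is refractory, which is what gives PARMS its allele specificity.

# 0-based plus-strand offsets where the primer's 3'-anchor binds.
# Returns the 0-based position of the primer's 3'-terminal base on the
# plus strand (for fwd primers) or of its plus-strand leftmost base (rev).
anchor_sites <- function(template_chars, anchor_chars, max_mm) {
  la <- length(anchor_chars)
  n <- length(template_chars)
  if (la > n) return(integer(0))
  starts <- which(template_chars == anchor_chars[la])  # match 3' base (fwd sense)
  starts <- starts - la + 1L
  starts <- starts[starts >= 1L]
  hits <- starts[vapply(starts, function(s) {
    sum(template_chars[s:(s + la - 1L)] != anchor_chars) <= max_mm
  }, TRUE)]
  hits - 1L
}

#' In-silico PCR
#'
#' Finds all forward-primer sites on the plus strand and pairs each with the
#' nearest downstream reverse-primer site within the maximum product length.
#' The product incorporates the primer sequences (so engineered dCAPS bases
#' and PARMS tails appear in the amplicon, as in a real reaction).
#'
#' @param template Template DNA (plus strand).
#' @param fwd,rev Primer sequences 5'->3' (rev primes the minus strand).
#'   Lowercase (engineered) bases are uppercased before matching.
#' @param cfg A [design_config()] supplying the binding parameters.
#' @return Character vector of amplicon sequences (empty = no product).
#' @export
virtual_pcr <- function(template, fwd, rev, cfg = design_config()) {
  template <- check_dna(template, "template", allow_ambiguity = FALSE)
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (!nzchar(fwd) || !nzchar(rev)) stop("primers must be nonempty")
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  la <- cfg$binding_anchor
  fwd_anchor <- strsplit(substr(fwd, max(1L, nchar(fwd) - la + 1L), nchar(fwd)),
                         "", fixed = TRUE)[[1]]
  # rev primer on the minus strand: its plus-strand footprint is rc(rev);
  # the 3'-anchor of rev corresponds to the leftmost bases of rc(rev)
  rev_rc <- revcomp(rev)
  rev_anchor <- strsplit(substr(rev_rc, 1L, min(la, nchar(rev_rc))),
                         "", fixed = TRUE)[[1]]
  fwd_hits <- anchor_sites(tch, fwd_anchor, cfg$binding_max_mismatch)
  # for rev, the exact-match base is the anchor's FIRST char on the plus strand
  rev_hits <- rev_anchor_sites(tch, rev_anchor, cfg$binding_max_mismatch)
  if (!length(fwd_hits) || !length(rev_hits)) return(character(0))
  out <- character(0)
  for (f0 in fwd_hits) {
    f3 <- f0 + length(fwd_anchor) - 1L       # 0-based pos of fwd 3' base
    cand <- rev_hits[rev_hits > f3]          # rev plus-strand start after fwd 3'
    if (!length(cand)) next
    r0 <- min(cand)
    r_end <- r0 + nchar(rev) - 1L
    # product length on the template frame
    span <- r_end - (f3 - nchar(fwd) + 1L) + 1L
    if (span > cfg$max_product) next
    inner <- if (r0 > f3 + 1L) {
      substr(template, f3 + 2L, r0)          # 1-based: bases between sites
    } else ""
    out <- c(out, paste0(fwd, inner, rev_rc))
  }
  out
}

rev_anchor_sites <- function(template_chars, anchor_chars, max_mm) {
  la <- length(anchor_chars)
  n <- length(template_chars)
  if (la > n) return(integer(0))
  starts <- which(template_chars == anchor_chars[1L])  # rev 3' base (plus frame)
  starts <- starts[starts + la - 1L <= n]
  hits <- starts[vapply(starts, function(s) {
    sum(template_chars[s:(s + la - 1L)] != anchor_chars) <= max_mm
  }, TRUE)]
  hits - 1L
}

#' Run a marker assay against one locus
#'
#' Simulates the assay end-to-end: PCR, then (for CAPS/dCAPS) restriction
#' digestion, then the gel or fluorescence read-out, and classifies the
#' result against the marker's expected patterns at the applicable gel
#' resolution (PAGE for Indel/dCAPS, agarose for CAPS).
#'
#' @param locus A [locus_sequence()] (or plain DNA string) to genotype.
#' @param marker A [marker_assay()].
#' @param cfg A [design_config()].
#' @return A list of class `band_pattern`: `marker`, `accession`,
#'   `fragments` (integer vector; empty = no amplification), and `call`
#'   (`"ref_class"`, `"alt_class"`, `"ambiguous"` or `"null"`).
#' @export
assay <- function(locus, marker, cfg = design_config()) {
  stopifnot(inherits(marker, "marker_assay"))
  if (inherits(locus, "locus_seq")) {
    template <- locus$seq; accession <- locus$accession
  } else {
    template <- check_dna(locus, "locus"); accession <- NA_character_
  }
  res <- if (marker$mtype == "PARMS") {
    assay_parms(template, marker, cfg)
  } else {
    assay_gel(template, marker, cfg)
  }
  structure(c(list(marker = marker$name, accession = accession), res),
            class = "band_pattern")
}

assay_gel <- function(template, marker, cfg) {
  amps <- virtual_pcr(template, marker$primers$F, marker$primers$R, cfg)
  if (!length(amps)) return(list(fragments = integer(0), call = "null"))
  amp <- amps[[1L]]
  res <- if (marker$mtype == "CAPS") cfg$gel_resolution_agarose else
    cfg$gel_resolution_page
  frags <- if (marker$mtype %in% c("CAPS", "dCAPS")) {
    digest(amp, marker$enzyme)
  } else {
    nchar(amp)
  }
  ref_hit <- patterns_match(frags, marker$expected$ref, res)
  alt_hit <- patterns_match(frags, marker$expected$alt, res)
  call <- if (ref_hit && alt_hit) "ambiguous"
  else if (ref_hit) "ref_class"
  else if (alt_hit) "alt_class"
  else "ambiguous"
  list(fragments = sort(as.integer(frags), decreasing = TRUE), call = call)
}

assay_parms <- function(template, marker, cfg) {
  amp_fc <- virtual_pcr(template, marker$primers$FC, marker$primers$R, cfg)
  amp_ft <- virtual_pcr(template, marker$primers$FT, marker$primers$R, cfg)
  fluor <- function(primer) {
    if (startsWith(toupper(primer), toupper(cfg$tail_fam))) "FAM"
    else if (startsWith(toupper(primer), toupper(cfg$tail_hex))) "HEX"
    else NA_character_
  }
  signals <- c(
    if (length(amp_fc)) fluor(marker$primers$FC),
    if (length(amp_ft)) fluor(marker$primers$FT)
  )
  frags <- as.integer(nchar(c(amp_fc, amp_ft)))
  if (!length(signals)) return(list(fragments = integer(0), call = "null"))
  if (length(unique(signals)) > 1L) {
    return(list(fragments = frags, call = "ambiguous"))
  }
  call <- if (identical(unique(signals), marker$expected$ref)) "ref_class"
  else if (identical(unique(signals), marker$expected$alt)) "alt_class"
  else "ambiguous"
  list(fragments = frags, call = call)
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("<band_pattern> %s on %s: [%s] -> %s\n", x$marker,
              x$accession %||% "?",
              paste(x$fragments, collapse = ";"), x$call))
  invisible(x)
}

#' Validate a marker's discriminating power on a panel
#'
#' Runs the assay on every panel accession and checks concordance with the
#' haplotype truth: members of the marker's target haplotypes must call
#' `alt_class`, all other named accessions `ref_class`; n.d. accessions are
#' exempt.  The marker additionally fails ("unresolvable") when its two
#' expected class patterns are not separated by the applicable gel
#' resolution.
#'
#' @param marker A [marker_assay()].
#' @param panel Named list of [locus_sequence()] (or named DNA vector).
#' @param truth A `haplotype_set` giving the true partition.
#' @param cfg A [design_config()].
#' @return A list: `passes` (logical), `reason` (when failing), and
#'   `report` (data.frame: accession, haplotype, fragments, call, expected,
#'   concordant).
#' @export
validate_marker <- function(marker, panel, truth, cfg = design_config()) {
  assign_map <- haplotype_assignments(truth)
  res <- if (marker$mtype == "CAPS") cfg$gel_resolution_agarose else
    cfg$gel_resolution_page
  resolvable <- if (marker$mtype == "PARMS") TRUE else
    !patterns_match(marker$expected$ref, marker$expected$alt, res)
  rows <- lapply(names(panel), function(a) {
    bp <- assay(panel[[a]], marker, cfg)
    hap <- unname(assign_map[a])
    if (is.na(hap)) hap <- "n.d."
    expected <- if (hap == "n.d.") NA_character_
    else if (hap %in% marker$target_haplotypes) "alt_class"
    else "ref_class"
    data.frame(accession = a, haplotype = hap,
               fragments = paste(bp$fragments, collapse = ";"),
               call = bp$call, expected = expected,
               concordant = is.na(expected) | identical(bp$call, expected),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ok <- all(report$concordant)
  passes <- ok && resolvable
  reason <- if (!resolvable) "unresolvable: class patterns within gel resolution"
  else if (!ok) paste("discordant calls:",
                      paste(report$accession[!report$concordant], collapse = ", "))
  else NA_character_
  list(passes = passes, reason = reason, report = report)
}
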