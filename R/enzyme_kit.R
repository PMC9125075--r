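# Restriction-enzyme model: IUPAC-aware site scanning and complete in-silico
# digestion.  Only top-strand cut positions are modeled; what matters for a
# CAPS/dCAPS read-out is the set of fragment lengths seen on a gel, not
# overhang geometry.

#' Construct a restriction enzyme
#'
#' @param name Enzyme name (e.g. `"TaqI"`).
#' @param recognition Recognition sequence as IUPAC DNA (length >= 4).
#' @param cut_offset Bases from the recognition 5' end to the top-strand cut,
#'   in `[0, nchar(recognition)]`.  Interrupted palindromes such as BglI
#'   (`GCCNNNN^NGGC`) cut inside the N tract.
#' @return An object of class `rest_enzyme`.
#' @examples
#' rest_enzyme("TaqI", "TCGA", 1)
#' @export
rest_enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- check_dna(recognition, "recognition")
  if (nchar(recognition) < 4L) {
    stop("recognition sequence must be at least 4 bp: ", name)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut offset ", cut_offset, " outside [0, ", nchar(recognition),
         "] for enzyme ", name)
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "rest_enzyme"
  )
}

#' @export
print.rest_enzyme <- function(x, ...) {
  rec <- x$recognition
  cat(sprintf("<rest_enzyme> %s  %s^%s\n", x$name,
              substr(rec, 1, x$cut_offset),
              substr(rec, x$cut_offset + 1, nchar(rec))))
  invisible(x)
}

is_palindromic_pattern <- function(recognition) {
  identical(recognition, revcomp(recognition))
}

#' Find restriction sites in a sequence
#'
#' Scans the top strand with IUPAC semantics.  For non-palindromic
#' recognitions the reverse-complement pattern is scanned as well and those
#' hits are flagged with `strand = "-"`; a double-stranded cutter cleaves at
#' such sites too.
#'
#' @param seq Concrete DNA (no ambiguity codes).
#' @param enzyme A [rest_enzyme()].
#' @return A data.frame with columns `start` (0-based site start on the top
#'   strand), `strand` (`"+"` or `"-"`), and `cut` (0-based top-strand cut
#'   position: a cut between bases `cut` and `cut + 1` of `seq`).
#' @examples
#' find_sites("AAATCGAAA", rest_enzyme("TaqI", "TCGA", 1))
#' @export
find_sites <- function(seq, enzyme) {
  seq <- check_dna(seq, "seq", allow_ambiguity = FALSE)
  stopifnot(inherits(enzyme, "rest_enzyme"))
  rec <- enzyme$recognition
  w <- nchar(rec)
  fwd <- iupac_match_starts(seq, rec)
  out <- data.frame(
    start = fwd,
    strand = rep("+", length(fwd)),
    cut = fwd + enzyme$cut_offset
  )
  if (!is_palindromic_pattern(rec)) {
    rc <- revcomp(rec)
    rev_hits <- iupac_match_starts(seq, rc)
    # top-strand cut of a site recognized on the bottom strand: the enzyme's
    # bottom-strand cut mirrors the top-strand one about the site.
    out <- rbind(out, data.frame(
      start = rev_hits,
      strand = rep("-", length(rev_hits)),
      cut = rev_hits + (w - enzyme$cut_offset)
    ))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Complete digestion of a sequence
#'
#' All recognition sites are cut (complete-digestion model, duplicate cut
#' positions collapsed); fragment lengths are returned 5' to 3' and always
#' sum to the input length.
#'
#' @inheritParams find_sites
#' @return Integer vector of fragment lengths; `length(seq)` itself when
#'   there is no site.
#' @examples
#' digest("AAATCGAAA", rest_enzyme("TaqI", "TCGA", 1))
#' @export
digest <- function(seq, enzyme) {
  seq <- check_dna(seq, "seq", allow_ambiguity = FALSE)
  n <- nchar(seq)
  stopifnot(n >= 1L)
  sites <- find_sites(seq, enzyme)
  cuts <- sort(unique(sites$cut))
  cuts <- cuts[cuts > 0L & cuts < n]   # end cuts produce no new fragment
  as.integer(diff(c(0L, cuts, n)))
}

# fast internal variant of the differential-site test: does any recognition
# site (either orientation) overlap 0-based position snp0?
site_overlaps <- function(seq, enzyme, snp0) {
  w <- nchar(enzyme$recognition)
  lo <- max(0L, snp0 - w + 1L)
  win <- substr(seq, lo + 1L, min(nchar(seq), snp0 + w))
  starts <- iupac_match_starts(win, enzyme$recognition)
  if (!is_palindromic_pattern(enzyme$recognition)) {
    starts <- c(starts, iupac_match_starts(win, revcomp(enzyme$recognition)))
  }
  rel <- snp0 - lo
  any(starts <= rel & rel < starts + w)
}

#' Classify a SNP's effect on a restriction site
#'
#' The two contexts are the same window around a SNP, differing at exactly one
#' base.  The classification reports which allele carries at least one
#' recognition site overlapping the SNP position (orientation-aware).
#'
#' @param context_ref,context_alt Equal-length DNA windows differing at one base.
#' @param enzyme A [rest_enzyme()].
#' @return One of `"ref_only"`, `"alt_only"`, `"both"`, `"neither"`.
#' @export
differential_site <- function(context_ref, context_alt, enzyme) {
  context_ref <- check_dna(context_ref, "context_ref", allow_ambiguity = FALSE)
  context_alt <- check_dna(context_alt, "context_alt", allow_ambiguity = FALSE)
  if (nchar(context_ref) != nchar(context_alt)) {
    stop("contexts must have equal length")
  }
  diffs <- which(strsplit(context_ref, "")[[1]] != strsplit(context_alt, "")[[1]])
  if (length(diffs) == 0L) stop("contexts are identical; not a SNP")
  if (length(diffs) > 1L) stop("contexts differ at more than one base")
  snp0 <- diffs - 1L   # 0-based
  ref_hit <- site_overlaps(context_ref, enzyme, snp0)
  alt_hit <- site_overlaps(context_alt, enzyme, snp0)
  if (ref_hit && alt_hit) "both"
  else if (ref_hit) "ref_only"
  else if (alt_hit) "alt_only"
  else "neither"
}
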