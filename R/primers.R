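# Deterministic primer-pair search under the package's design constraints.
# The paper-level pipeline delegates primer placement here; choices are
# reproducible by construction (smallest amplicon, then highest minimum Tm,
# then leftmost forward primer).

#' Marker-design configuration
#'
#' Tunable parameters of the design cascade.  Defaults encode the study
#' conditions: indels of 5-30 bp are given priority and typed on 4%
#' polyacrylamide gels (about 4-bp resolution); CAPS amplicons run 100-500 bp
#' on 2% agarose (about 20-bp resolution); dCAPS and Indel amplicons run
#' 100-300 bp.  The two PARMS tails are the universal FAM/HEX primer tails.
#'
#' @param indel_min,indel_max Indel size bounds (bp) for the Indel stage.
#' @param indel_amplicon,caps_amplicon,dcaps_amplicon,parms_amplicon
#'   Amplicon length ranges `c(min, max)`.
#' @param primer_len Primer length range.
#' @param tm_range Primer Tm range (degrees C).
#' @param gc_range Primer GC range (fractions in `[0,1]`).
#' @param max_dcaps_mismatches Engineered mismatches allowed in a dCAPS primer.
#' @param tail_fam,tail_hex Universal fluorophore tails for PARMS primers.
#' @param gel_resolution_page,gel_resolution_agarose Size difference (bp)
#'   resolvable on the two gel systems.
#' @param allow_structural_override Permit Indel markers for variants outside
#'   the size bounds (large structural variants), with relaxed amplicon
#'   bounds and a warning.
#' @param binding_max_mismatch,binding_anchor In-silico PCR binding model:
#'   a primer binds where its 3'-terminal base matches exactly and at most
#'   `binding_max_mismatch` of its 3'-most `binding_anchor` bases mismatch
#'   (5' tails beyond the anchor, e.g. PARMS tails, dangle).
#' @param max_product In-silico PCR maximum product length (bp).
#' @return A list of class `design_config`.
#' @export
design_config <- function(indel_min = 5L, indel_max = 30L,
                          indel_amplicon = c(100L, 300L),
                          caps_amplicon = c(100L, 500L),
                          dcaps_amplicon = c(100L, 300L),
                          parms_amplicon = c(100L, 300L),
                          primer_len = c(18L, 24L),
                          tm_range = c(52, 62),
                          gc_range = c(0.35, 0.65),
                          max_dcaps_mismatches = 1L,
                          tail_fam = "GAAGGTGACCAAGTTCATGCT",
                          tail_hex = "GAAGGTCGGAGTCAACGGATT",
                          gel_resolution_page = 4L,
                          gel_resolution_agarose = 20L,
                          allow_structural_override = TRUE,
                          binding_max_mismatch = 1L,
                          binding_anchor = 20L,
                          max_product = 5000L) {
  stopifnot(indel_min >= 1L, indel_min <= indel_max,
            indel_amplicon[1] <= indel_amplicon[2],
            caps_amplicon[1] <= caps_amplicon[2],
            dcaps_amplicon[1] <= dcaps_amplicon[2],
            primer_len[1] <= primer_len[2])
  structure(
    list(indel_min = as.integer(indel_min), indel_max = as.integer(indel_max),
         indel_amplicon = as.integer(indel_amplicon),
         caps_amplicon = as.integer(caps_amplicon),
         dcaps_amplicon = as.integer(dcaps_amplicon),
         parms_amplicon = as.integer(parms_amplicon),
         primer_len = as.integer(primer_len), tm_range = tm_range,
         gc_range = gc_range,
         max_dcaps_mismatches = as.integer(max_dcaps_mismatches),
         tail_fam = tail_fam, tail_hex = tail_hex,
         gel_resolution_page = as.integer(gel_resolution_page),
         gel_resolution_agarose = as.integer(gel_resolution_agarose),
         allow_structural_override = isTRUE(allow_structural_override),
         binding_max_mismatch = as.integer(binding_max_mismatch),
         binding_anchor = as.integer(binding_anchor),
         max_product = as.integer(max_product)),
    class = "design_config"
  )
}

# Per-primer feasibility: length is implied by construction.
primer_ok <- function(seq, cfg) {
  gc <- gc_content(seq)
  if (is.na(gc) || gc < cfg$gc_range[1] || gc > cfg$gc_range[2]) return(FALSE)
  if (max_homopolymer(seq) > 4L) return(FALSE)
  tm <- tm_nn(seq)
  tm >= cfg$tm_range[1] && tm <= cfg$tm_range[2]
}

# TRUE when the 3'-terminal 4-mers of the two primers can anneal to each
# other (>= 4-bp 3' self-complement between partners).
primer_3p_clash <- function(a, b) {
  ta <- substr(a, nchar(a) - 3L, nchar(a))
  tb <- substr(b, nchar(b) - 3L, nchar(b))
  identical(ta, revcomp(tb))
}

# Enumerate all constraint-passing primers on one strand of `template`.
# Returns data.frame(start, end, len, seq, tm) with 1-based coordinates.
#
# Tm is computed from cumulative nearest-neighbor sums over the template, so
# each candidate costs O(1); the duplex NN model is strand-symmetric
# (Tm(revcomp(s)) == Tm(s)), so reverse primers reuse the plus-strand sums.
enumerate_primers <- function(template, cfg, region = c(1L, nchar(template)),
                              reverse = FALSE) {
  n <- nchar(template)
  empty <- data.frame(start = integer(0), end = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0))
  lo <- max(1L, region[1]); hi <- min(n, region[2])
  if (hi - lo + 1L < cfg$primer_len[1]) return(empty)
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  keys <- paste0(tch[-n], tch[-1L])
  dh_vals <- unname(NN_DH[keys]); ds_vals <- unname(NN_DS[keys])
  dh_vals[is.na(dh_vals)] <- 0; ds_vals[is.na(ds_vals)] <- 0  # N-containing
  dh_run <- c(0, cumsum(dh_vals))   # candidates with N are dropped later
  ds_run <- c(0, cumsum(ds_vals))
  is_gc <- tch %in% c("G", "C")
  gc_run <- c(0L, cumsum(is_gc))
  r_gas <- 1.987
  conc_term <- r_gas * log(0.25e-6 / 4)
  salt <- 0.368 * log(0.05)
  out <- list()
  for (len in cfg$primer_len[1]:cfg$primer_len[2]) {
    if (hi - lo + 1L < len) next
    s <- lo:(hi - len + 1L)
    e <- s + len - 1L
    gc <- (gc_run[e + 1L] - gc_run[s]) / len
    keep <- gc >= cfg$gc_range[1] & gc <= cfg$gc_range[2]
    if (!any(keep)) next
    s <- s[keep]; e <- e[keep]
    dh <- dh_run[e] - dh_run[s] +
      ifelse(is_gc[s], 0.1, 2.3) + ifelse(is_gc[e], 0.1, 2.3)
    ds <- ds_run[e] - ds_run[s] +
      ifelse(is_gc[s], -2.8, 4.1) + ifelse(is_gc[e], -2.8, 4.1) +
      salt * (len - 1L)
    tm <- dh * 1000 / (ds + conc_term) - 273.15
    keep <- !is.na(tm) & tm >= cfg$tm_range[1] & tm <= cfg$tm_range[2]
    if (!any(keep)) next
    s <- s[keep]; e <- e[keep]; tm <- tm[keep]
    seqs <- substring(template, s, e)
    keep <- !grepl("N|A{5}|C{5}|G{5}|T{5}", seqs)
    if (!any(keep)) next
    seqs <- seqs[keep]
    if (reverse) seqs <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      start = s[keep], end = e[keep], len = len, seq = seqs,
      tm = tm[keep], stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Design a primer pair on a template
#'
#' Finds a forward/reverse primer pair whose amplicon covers `must_span`
#' and lies within `amplicon_range`.  Constraints: primer length and Tm in
#' the configured ranges (nearest-neighbor Tm, Wallace rule below 14 nt),
#' GC content in range, no mononucleotide run longer than 4, and no 4-bp
#' 3'-end complementarity between the partners.  The choice is
#' deterministic: smallest amplicon first, then the pair with the highest
#' minimum Tm, then the leftmost forward primer.
#'
#' @param template Template DNA (plus strand).
#' @param must_span `c(lo, hi)` 1-based inclusive interval the amplicon
#'   interior must cover; primers must not overlap it.
#' @param amplicon_range `c(min, max)` product length bounds.
#' @param cfg A [design_config()].
#' @param avoid Optional list of `c(lo, hi)` template intervals the amplicon
#'   must not overlap (e.g. positions of other segregating variants, which
#'   would distort fragment sizes or primer binding in part of the panel).
#' @return A list `(fwd, rev, fwd_start, rev_end, amplicon)` with primer
#'   sequences (rev given 5'->3' on the minus strand), or a `design_failure`
#'   naming the binding constraint when infeasible.
#' @export
design_primer_pair <- function(template, must_span, amplicon_range,
                               cfg = design_config(), avoid = NULL) {
  template <- check_dna(template, "template")
  n <- nchar(template)
  if (n < amplicon_range[1]) {
    return(design_failure("template shorter than the minimum amplicon"))
  }
  must_span <- as.integer(must_span)
  fw <- enumerate_primers(template, cfg, region = c(1L, must_span[1] - 1L))
  rv <- enumerate_primers(template, cfg, region = c(must_span[2] + 1L, n),
                          reverse = TRUE)
  if (!nrow(fw)) return(design_failure("no feasible forward primer 5' of the target"))
  if (!nrow(rv)) return(design_failure("no feasible reverse primer 3' of the target"))
  amp <- outer(rv$end, fw$start, `-`) + 1L          # [rev, fwd]
  ok <- amp >= amplicon_range[1] & amp <= amplicon_range[2]
  if (!any(ok)) return(design_failure("no primer pair yields an amplicon in range"))
  idx <- which(ok, arr.ind = TRUE)
  cand <- data.frame(
    ri = idx[, 1], fi = idx[, 2],
    amplicon = amp[idx],
    min_tm = pmin(rv$tm[idx[, 1]], fw$tm[idx[, 2]]),
    fwd_start = fw$start[idx[, 2]]
  )
  if (length(avoid)) {
    rev_end <- rv$end[cand$ri]
    keep <- !Reduce(`|`, lapply(avoid, function(iv) {
      cand$fwd_start <= iv[2] & rev_end >= iv[1]
    }))
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) {
      return(design_failure("every in-range amplicon spans another variant"))
    }
  }
  cand <- cand[order(cand$amplicon, -cand$min_tm, cand$fwd_start), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    f <- fw[cand$fi[i], ]; r <- rv[cand$ri[i], ]
    if (primer_3p_clash(f$seq, r$seq)) next
    return(list(fwd = f$seq, rev = r$seq,
                fwd_start = f$start, rev_end = r$end,
                amplicon = cand$amplicon[i]))
  }
  design_failure("all in-range pairs show 3'-end complementarity")
}

#' Design-stage failure marker
#'
#' @param reason Human-readable constraint that could not be met.
#' @return An object of class `design_failure`.
#' @keywords internal
design_failure <- function(reason) {
  structure(list(reason = reason), class = "design_failure")
}

#' @export
print.design_failure <- function(x, ...) {
  cat("<design_failure>", x$reason, "\n")
  invisible(x)
}

is_failure <- function(x) inherits(x, "design_failure")

failure_reason <- function(x) if (is_failure(x)) x$reason else NULL
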