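# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and Biostrings) so that agreement is evidence,
# not circularity.

# Exhaustive global-alignment optimum with affine gaps: plain recursion over
# the three pending-operation states, no vectorized DP, no heuristics.
# Scores: match/mismatch per pair; a gap of length L costs open + L * extend.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {   # gap in b (delete from a)
      open <- if (state == "da") 0 else gap_open
      best <- max(best, open + gap_extend + rec(i + 1, j, "da"))
    }
    if (j <= length(bv)) {   # gap in a (insert from b)
      open <- if (state == "db") 0 else gap_open
      best <- max(best, open + gap_extend + rec(i, j + 1, "db"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# Tiny independent IUPAC matcher for the dCAPS brute-force oracle.
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_site_match <- function(seq, pattern, at) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (at + length(pv) - 1 > nchar(seq)) return(FALSE)
  sv <- strsplit(substr(seq, at, at + length(pv) - 1), "", fixed = TRUE)[[1]]
  all(mapply(function(s, p) s %in% oracle_iupac[[p]], sv, pv))
}

# any recognition-site occurrence (either orientation) overlapping 1-based
# position `pos` of `seq`?
oracle_site_over <- function(seq, recognition, pos) {
  w <- nchar(recognition)
  pats <- unique(c(recognition, oracle_rc(recognition)))
  for (st in max(1, pos - w + 1):pos) {
    for (p in pats) if (oracle_site_match(seq, p, st)) return(TRUE)
  }
  FALSE
}

# Brute-force dCAPS search on a toy plus-strand context: all primer 3' ends
# within w-1 bases 5' of the SNP, all mismatch offsets 2..6 from the 3' end,
# all 3 substitutions; returns data.frames of (end, mm_offset, base, enzyme)
# whose engineered context carries a site overlapping the SNP for exactly
# one allele.
oracle_dcaps_search <- function(template, snp_pos, ref_base, alt_base,
                                enzymes) {
  hits <- list()
  for (ei in seq_along(enzymes)) {
    rec <- enzymes[[ei]]$recognition
    w <- nchar(rec)
    for (e in (snp_pos - 1):(snp_pos - w + 1)) {
      if (e < 1) next
      for (m in 2:6) {
        at <- e - m + 1
        if (at < 1) next
        cur <- substr(template, at, at)
        for (b in setdiff(c("A", "C", "G", "T"), cur)) {
          ctx <- template
          substr(ctx, at, at) <- b
          ref_ctx <- ctx; substr(ref_ctx, snp_pos, snp_pos) <- ref_base
          alt_ctx <- ctx; substr(alt_ctx, snp_pos, snp_pos) <- alt_base
          r <- oracle_site_over(ref_ctx, rec, snp_pos)
          a <- oracle_site_over(alt_ctx, rec, snp_pos)
          if (xor(r, a)) {
            hits[[length(hits) + 1]] <- data.frame(
              end = e, mm_offset = m, base = b,
              enzyme = enzymes[[ei]]$name,
              class = if (r) "ref_only" else "alt_only",
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(end = integer(0), mm_offset = integer(0),
                      base = character(0), enzyme = character(0),
                      class = character(0)))
  }
  do.call(rbind, hits)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
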