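# Low-level DNA string helpers shared across modules.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented code-for-code (e.g. `R` to `Y`).
#'
#' @param seq A single DNA string.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("ACGT")
#' revcomp("CTNAG")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' @keywords internal
check_dna <- function(seq, what = "sequence", allow_ambiguity = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  allowed <- if (allow_ambiguity) names(IUPAC_CODES) else c("A", "C", "G", "T", "N")
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop(what, " contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  }
  seq
}

# Translate an IUPAC pattern to a fixed-width regex character-class pattern.
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC pattern characters: ", paste(bad, collapse = ", "))
  }
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

# All start offsets (0-based) of IUPAC `pattern` in concrete `seq`,
# overlapping matches included (lookahead trick).
iupac_match_starts <- function(seq, pattern) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' GC content of a sequence
#'
#' @param seq A single DNA string.
#' @return Fraction of G+C bases, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!length(chars)) return(NA_real_)
  sum(chars %in% c("G", "C")) / length(chars)
}

# Longest mononucleotide run.
max_homopolymer <- function(seq) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  if (!length(r$lengths)) 0L else max(r$lengths)
}
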