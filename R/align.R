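# Global alignment of a panel accession's locus to the reference locus.
# Needleman-Wunsch with affine gaps, delegated to Biostrings; the default
# scoring (match +2, mismatch -3, gap open -5, gap extend -2 per base)
# deliberately favors one long contiguous indel over fragmented gaps, which
# is how structural variants in gene regions are conventionally described.

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).  A
#'   gap of length L contributes `gap_open + L * gap_extend`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Globally align a query locus to the reference locus
#'
#' @param query,ref [locus_sequence()] objects for the same gene; `ref` is
#'   the reference accession's locus.
#' @param scoring An [align_params()].
#' @return A list of class `locus_alignment` with the gapped `ref` and
#'   `query` strings, the alignment `score`, and the two locus objects.
#'   Loci beyond ~20 kb are refused: at that scale (or for multi-kb
#'   structural differences) supply variants through the variant-table
#'   input path instead.
#' @export
align_to_reference <- function(query, ref, scoring = align_params()) {
  stopifnot(inherits(query, "locus_seq"), inherits(ref, "locus_seq"))
  if (!identical(query$gene_id, ref$gene_id)) {
    stop("query and ref are from different genes: ",
         query$gene_id, " vs ", ref$gene_id)
  }
  if (nchar(query$seq) == 0L || nchar(ref$seq) == 0L) {
    stop("cannot align zero-length sequence")
  }
  if (max(nchar(query$seq), nchar(ref$seq)) > 20000L) {
    stop("locus exceeds the 20-kb practical alignment bound; ",
         "use the variant-table input path for such loci")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref$seq), Biostrings::DNAString(query$seq),
    substitutionMatrix = sm,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    type = "global"
  )
  structure(
    list(ref_aln = as.character(Biostrings::alignedPattern(pa)),
         query_aln = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa),
         ref = ref, query = query, scoring = scoring),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %s vs %s, %d columns, score %.1f\n",
              x$ref$gene_id, x$query$accession, x$ref$accession,
              nchar(x$ref_aln), x$score))
  invisible(x)
}
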