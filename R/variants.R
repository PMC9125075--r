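# Variant calling from locus alignments, ATG-relative coordinates, and
# gene-region annotation.
#
# Position convention (no zero): +1 is the A of the ATG, -1 the base
# immediately 5' of it.  A variant's position is the first affected
# reference base; an insertion sits immediately 5' of the base at its
# position.  Indels are left-aligned in repeat tracts, as in VCF practice.

#' Convert a locus offset to an ATG-relative position
#'
#' @param locus_offset 0-based index into the locus sequence.
#' @param locus A [locus_sequence()].
#' @return Signed ATG-relative position (never 0).
#' @examples
#' # with atg_offset = 2000: offset 2000 -> +1, 2001 -> +2, 1999 -> -1
#' @export
label_position <- function(locus_offset, locus) {
  stopifnot(inherits(locus, "locus_seq"))
  locus_offset <- as.integer(locus_offset)
  if (any(locus_offset < 0L) || any(locus_offset >= nchar(locus$seq))) {
    stop("locus offset out of range [0, ", nchar(locus$seq) - 1L, "]")
  }
  ifelse(locus_offset >= locus$atg_offset,
         locus_offset - locus$atg_offset + 1L,
         locus_offset - locus$atg_offset)
}

#' Convert an ATG-relative position back to a locus offset
#'
#' Inverse of [label_position()].
#'
#' @param position Signed ATG-relative position (no 0).
#' @param locus A [locus_sequence()].
#' @return 0-based locus offset.
#' @export
unlabel_position <- function(position, locus) {
  stopifnot(inherits(locus, "locus_seq"))
  position <- as.integer(position)
  if (any(position == 0L)) stop("position 0 is not defined (convention has no zero)")
  off <- ifelse(position > 0L, position - 1L + locus$atg_offset,
                position + locus$atg_offset)
  if (any(off < 0L) || any(off >= nchar(locus$seq))) {
    stop("position maps outside the locus")
  }
  as.integer(off)
}

#' Annotate an ATG-relative position with its gene region
#'
#' Returns `"5U"` for positions 5' of the ATG, `"3U"` for positions past the
#' stop codon, and `"E<k>"`/`"I<k>"` for exonic/intronic positions, with
#' ordinals in transcription order.  The upstream flank is labelled 5U
#' wholesale (fixed-flank usage; not a transcript UTR in the strict sense).
#'
#' @param position Signed ATG-relative position (no 0).
#' @param model A [gene_model()].
#' @return Region tag string.
#' @examples
#' # position +1 is always "E1"
#' @export
annotate_region <- function(position, model) {
  stopifnot(inherits(model, "gene_model"))
  position <- as.integer(position)
  if (position == 0L) stop("position 0 is not defined (convention has no zero)")
  if (position < 0L) return("5U")
  # genic coordinates in transcription orientation, ATG-relative
  ex <- model$exons
  if (model$strand == "+") {
    starts <- ex[, 1] - model$atg_pos + 1L
    ends <- ex[, 2] - model$atg_pos + 1L
    genic_end <- model$stop_end - model$atg_pos + 1L
  } else {
    starts <- model$atg_pos - ex[, 2] + 1L
    ends <- model$atg_pos - ex[, 1] + 1L
    genic_end <- model$atg_pos - model$stop_end + 1L
  }
  if (position > genic_end) return("3U")
  for (k in seq_len(nrow(ex))) {
    if (position >= starts[k] && position <= ends[k]) return(paste0("E", k))
    if (k < nrow(ex) && position > ends[k] && position < starts[k + 1L]) {
      return(paste0("I", k))
    }
  }
  stop("position +", position, " not covered by the gene model")
}

#' Construct a variant record
#'
#' @param position ATG-relative position of the first affected reference
#'   base (for insertions, the reference base immediately 3' of the
#'   insertion point).
#' @param vtype One of `"SNP"`, `"INS"`, `"DEL"`, `"SUB"` (`SUB` = a
#'   replacement, e.g. 637 bp swapped for 12 bp).
#' @param ref_allele,alt_allele DNA strings; `"-"` denotes the empty allele
#'   (the ref of an INS, the alt of a DEL).
#' @param region Optional region tag from [annotate_region()].
#' @return One-row data.frame with columns `position`, `vtype`, `ref_allele`,
#'   `alt_allele`, `region`, `size_delta`.
#' @export
variant <- function(position, vtype, ref_allele, alt_allele, region = NA_character_) {
  vtype <- match.arg(vtype, c("SNP", "INS", "DEL", "SUB"))
  position <- as.integer(position)
  if (position == 0L) stop("variant position 0 is not defined")
  ref_len <- if (identical(ref_allele, "-")) 0L else nchar(ref_allele)
  alt_len <- if (identical(alt_allele, "-")) 0L else nchar(alt_allele)
  ok <- switch(vtype,
    SNP = ref_len == 1L && alt_len == 1L,
    INS = ref_len == 0L && alt_len >= 1L,
    DEL = ref_len >= 1L && alt_len == 0L,
    SUB = ref_len >= 1L && alt_len >= 1L && !(ref_len == 1L && alt_len == 1L)
  )
  if (!ok) stop("alleles inconsistent with vtype ", vtype)
  data.frame(position = position, vtype = vtype,
             ref_allele = ref_allele, alt_allele = alt_allele,
             region = region, size_delta = alt_len - ref_len,
             stringsAsFactors = FALSE)
}

variant_id <- function(v) {
  paste0(v$position, ":", v$vtype, ":", v$ref_allele, ">", v$alt_allele)
}

#' Call variants from a locus alignment
#'
#' Walks the alignment columns and reports differences against the reference.
#' Runs of adjacent gap columns are merged into single insertions/deletions;
#' a mixed run containing both inserted and deleted bases becomes one
#' replacement (`SUB`).  Isolated mismatch columns are reported as SNPs.
#' Indels are left-aligned in repeat tracts and positioned at the first
#' affected reference base, ATG-relative.  Variants whose alleles contain
#' `N` are flagged (`has_n = TRUE`); marker design excludes them.
#'
#' @param alignment A `locus_alignment` from [align_to_reference()].
#' @param model Optional [gene_model()]; when given, each variant's `region`
#'   is annotated.
#' @return Data.frame of variants (zero rows for identical sequences), sorted
#'   by reference offset, with an extra `has_n` column.
#' @export
call_variants <- function(alignment, model = NULL) {
  stopifnot(inherits(alignment, "locus_alignment"))
  ref_ch <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1]]
  qry_ch <- strsplit(alignment$query_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(ref_ch) == length(qry_ch))
  n <- length(ref_ch)
  is_gap <- (ref_ch == "-") | (qry_ch == "-")
  is_diff <- is_gap | (ref_ch != qry_ch)
  # reference offset (0-based) consumed before each column
  ref_off <- cumsum(ref_ch != "-") - as.integer(ref_ch != "-")
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is_diff[i]) { i <- i + 1L; next }
    j <- i
    if (is_gap[i]) {
      # maximal run of difference columns containing the gap block; extend
      # while columns are gaps (mismatch columns sandwiched between gaps of
      # the same event get absorbed only if they are themselves gap columns)
      while (j < n && is_gap[j + 1L]) j <- j + 1L
      ref_seg <- paste(ref_ch[i:j][ref_ch[i:j] != "-"], collapse = "")
      qry_seg <- paste(qry_ch[i:j][qry_ch[i:j] != "-"], collapse = "")
      ev <- normalize_indel(ref_seg, qry_seg, ref_off[i], alignment$ref$seq)
      out[[length(out) + 1L]] <- ev
    } else {
      out[[length(out) + 1L]] <- list(
        ref_off = ref_off[i], vtype = "SNP",
        ref_allele = ref_ch[i], alt_allele = qry_ch[i]
      )
    }
    i <- j + 1L
  }
  # merge adjacent DEL+INS pairs (no intervening match) into SUB
  out <- merge_adjacent_events(out)
  if (!length(out)) {
    return(cbind(variant(1, "SNP", "A", "A")[0, ], has_n = logical(0)))
  }
  ref_locus <- alignment$ref
  rows <- lapply(out, function(ev) {
    pos <- label_position(ev$ref_off, ref_locus)
    reg <- if (!is.null(model)) annotate_region(pos, model) else NA_character_
    v <- variant(pos, ev$vtype, ev$ref_allele, ev$alt_allele, reg)
    v$has_n <- grepl("N", paste0(ev$ref_allele, ev$alt_allele), fixed = TRUE)
    v
  })
  res <- do.call(rbind, rows)
  res[order(vapply(out, `[[`, 0, "ref_off")), , drop = FALSE]
}

# Classify a gap-block event and left-align pure indels in repeat tracts.
# ref_off0: 0-based reference offset of the first reference base of the block
# (for pure insertions, of the reference base following the insertion point).
normalize_indel <- function(ref_seg, qry_seg, ref_off0, ref_seq) {
  if (nchar(ref_seg) > 0L && nchar(qry_seg) > 0L) {
    return(list(ref_off = ref_off0, vtype = "SUB",
                ref_allele = ref_seg, alt_allele = qry_seg))
  }
  if (nchar(ref_seg) > 0L) {        # deletion of ref_seg at ref_off0
    off <- ref_off0
    seg <- ref_seg
    while (off > 0L) {
      prev <- substr(ref_seq, off, off)          # ref base at offset off-1
      if (prev == substr(seg, nchar(seg), nchar(seg))) {
        seg <- paste0(prev, substr(seg, 1L, nchar(seg) - 1L))
        off <- off - 1L
      } else break
    }
    return(list(ref_off = off, vtype = "DEL", ref_allele = seg, alt_allele = "-"))
  }
  # insertion of qry_seg before reference base at ref_off0
  off <- ref_off0
  seg <- qry_seg
  while (off > 0L) {
    prev <- substr(ref_seq, off, off)
    if (prev == substr(seg, nchar(seg), nchar(seg))) {
      seg <- paste0(prev, substr(seg, 1L, nchar(seg) - 1L))
      off <- off - 1L
    } else break
  }
  list(ref_off = off, vtype = "INS", ref_allele = "-", alt_allele = seg)
}

merge_adjacent_events <- function(events) {
  if (length(events) < 2L) return(events)
  merged <- list(events[[1L]])
  for (ev in events[-1L]) {
    last <- merged[[length(merged)]]
    last_ref_len <- if (identical(last$ref_allele, "-")) 0L else nchar(last$ref_allele)
    adjacent <- ev$ref_off == last$ref_off + last_ref_len
    both_indel <- last$vtype %in% c("INS", "DEL") && ev$vtype %in% c("INS", "DEL") &&
      last$vtype != ev$vtype
    if (adjacent && both_indel) {
      ref_seg <- paste0(
        if (identical(last$ref_allele, "-")) "" else last$ref_allele,
        if (identical(ev$ref_allele, "-")) "" else ev$ref_allele
      )
      alt_seg <- paste0(
        if (identical(last$alt_allele, "-")) "" else last$alt_allele,
        if (identical(ev$alt_allele, "-")) "" else ev$alt_allele
      )
      merged[[length(merged)]] <- list(
        ref_off = last$ref_off, vtype = "SUB",
        ref_allele = ref_seg, alt_allele = alt_seg
      )
    } else {
      merged[[length(merged) + 1L]] <- ev
    }
  }
  merged
}

#' Write / read a variant table
#'
#' TSV with columns `gene`, `accession`, `position`, `vtype`, `ref`, `alt`,
#' `region` — the interchange form for pre-computed variants (e.g. for
#' structural variants too large to align).
#'
#' @param variants Data.frame as returned by [call_variants()], plus
#'   `gene` and `accession` columns (added if missing from the arguments).
#' @param path File path.
#' @param gene,accession Filled in when not already columns.
#' @return `path` (write) or the data.frame (read).
#' @export
write_variant_table <- function(variants, path, gene = NA, accession = NA) {
  df <- data.frame(
    gene = if ("gene" %in% names(variants)) variants$gene else gene,
    accession = if ("accession" %in% names(variants)) variants$accession else accession,
    position = variants$position, vtype = variants$vtype,
    ref = variants$ref_allele, alt = variants$alt_allele,
    region = variants$region, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = "NA")
  need <- c("gene", "accession", "position", "vtype", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- variant(df$position[i], df$vtype[i], df$ref[i], df$alt[i],
                 if ("region" %in% names(df)) df$region[i] else NA_character_)
    cbind(gene = df$gene[i], accession = df$accession[i], v)
  })
  do.call(rbind, rows)
}
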