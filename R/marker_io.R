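# Marker-table interchange: a TSV mirroring the published marker-table
# layout (one row per primer; marker-level fields carried on the first row
# of each marker and blank on continuation rows).  Reading then writing a
# table reproduces it byte-for-byte.

MARKER_TABLE_COLS <- c("gene", "variation_position", "marker_type",
                       "marker_name", "primer_role", "primer_seq",
                       "reference_size", "enzyme", "target_haplotypes")

#' Read a marker table
#'
#' @param path TSV file in the package's marker-table layout (see
#'   [write_marker_table()]); `#` lines are comments.
#' @param catalog An `enzyme_catalog` used to resolve enzyme names.
#' @return List of [marker_assay()] objects.
#' @export
read_marker_table <- function(path, catalog = read_enzyme_catalog()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (!all(MARKER_TABLE_COLS %in% names(df))) {
    stop("marker table needs columns: ", paste(MARKER_TABLE_COLS, collapse = ", "))
  }
  df[is.na(df)] <- ""
  # fill marker-level fields down over continuation rows
  fill <- function(x) {
    for (i in seq_along(x)) if (!nzchar(x[i]) && i > 1L) x[i] <- x[i - 1L]
    x
  }
  grp <- fill(df$marker_name)
  out <- list()
  for (nm in unique(grp)) {
    rows <- df[grp == nm, , drop = FALSE]
    head_row <- rows[1L, ]
    mtype <- head_row$marker_type
    primers <- as.list(rows$primer_seq)
    names(primers) <- rows$primer_role
    pos <- as.integer(gsub("–|−", "-", head_row$variation_position))
    enc <- head_row$reference_size
    enzyme <- NULL
    if (nzchar(head_row$enzyme)) enzyme <- catalog_enzyme(catalog, head_row$enzyme)
    expected <- if (mtype == "PARMS") {
      list(ref = "FAM", alt = "HEX")
    } else {
      parse_size_encoding(enc, mtype)[c("ref", "alt")]
    }
    tv <- marker_target_variant(pos, mtype, enc)
    targets <- trimws(strsplit(head_row$target_haplotypes, ",")[[1]])
    out[[nm]] <- marker_assay(
      name = nm, gene_id = head_row$gene, mtype = mtype,
      target_variant = tv, target_haplotypes = targets,
      primers = primers, enzyme = enzyme, expected = expected,
      size_encoding = enc, stage = mtype
    )
  }
  out
}

# Reconstruct a placeholder target variant from a table row: the table gives
# the position and marker type but not the allele sequences, so indel
# alleles are represented as N-runs of the encoded size.
marker_target_variant <- function(pos, mtype, enc) {
  if (mtype == "Indel") {
    delta <- parse_size_encoding(enc, "Indel")$delta
    if (delta > 0L) variant(pos, "INS", "-", strrep("N", delta))
    else variant(pos, "DEL", strrep("N", -delta), "-")
  } else {
    variant(pos, "SNP", "N", "N")
  }
}

#' Write a marker table
#'
#' Inverse of [read_marker_table()]: emits one row per primer with the
#' marker-level columns on the first row of each marker only.
#'
#' @param markers List of [marker_assay()] objects.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  rows <- lapply(markers, function(m) {
    roles <- names(m$primers)
    n <- length(roles)
    data.frame(
      gene = c(m$gene_id, rep("", n - 1L)),
      variation_position = c(format_signed(m$target_variant$position),
                             rep("", n - 1L)),
      marker_type = c(m$mtype, rep("", n - 1L)),
      marker_name = c(m$name, rep("", n - 1L)),
      primer_role = roles,
      primer_seq = unlist(m$primers, use.names = FALSE),
      reference_size = c(if (m$mtype == "PARMS") "" else m$size_encoding,
                         rep("", n - 1L)),
      enzyme = c(if (is.null(m$enzyme)) "" else m$enzyme$name, rep("", n - 1L)),
      target_haplotypes = c(paste(m$target_haplotypes, collapse = ", "),
                            rep("", n - 1L)),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_signed <- function(x) sprintf("%+d", x)
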