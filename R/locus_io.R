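# Readers/writers for panel sequences, gene models and enzyme catalogs, and
# extraction of the fixed analysis region around a gene.
#
# Coordinate conventions: genomic inputs are 1-based inclusive (GFF
# convention); internal offsets into an extracted locus are 0-based.

#' Construct a gene model
#'
#' Describes one gene on a genomic sequence: the position of the A of the ATG
#' start codon, the last base of the stop codon, and the exon intervals in
#' transcription order.  Minus-strand genes are handled downstream by
#' reverse-complementing the extracted locus, so all locus-level logic sees a
#' plus-oriented gene.
#'
#' @param gene_id Gene identifier (e.g. a LOC accession).
#' @param seq_id Name of the chromosome/contig the coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param atg_pos 1-based genomic coordinate of the A of ATG.
#' @param stop_end 1-based genomic coordinate of the last stop-codon base.
#' @param exons Two-column matrix (start, end), 1-based inclusive, rows in
#'   transcription order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, atg_pos, stop_end, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1] > exons[, 2])) stop("exon start > end")
  atg_pos <- as.integer(atg_pos); stop_end <- as.integer(stop_end)
  # transcription order: ascending coordinates on +, descending on -
  ord <- order(exons[, 1], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L) {
    s <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(s[-1, 1] <= s[-nrow(s), 2])) stop("exons overlap")
  }
  within <- function(p, ex) p >= ex[1] && p <= ex[2]
  if (!within(atg_pos, exons[1, ])) stop("atg_pos not in the first exon")
  if (!within(stop_end, exons[nrow(exons), ])) stop("stop_end not in the last exon")
  if (strand == "+" && atg_pos > stop_end) stop("atg_pos > stop_end on + strand")
  if (strand == "-" && atg_pos < stop_end) stop("atg_pos < stop_end on - strand")
  structure(
    list(gene_id = gene_id, seq_id = seq_id, strand = strand,
         atg_pos = atg_pos, stop_end = stop_end, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s)\n",
              x$gene_id, x$seq_id, min(x$exons), max(x$exons), x$strand,
              nrow(x$exons)))
  invisible(x)
}

#' Read a gene model from TSV or GFF3
#'
#' Two formats are accepted.  A 4+-column TSV with a header
#' `gene_id seq_id strand atg_pos stop_end exons` where `exons` is a
#' comma-separated list of `start-end` intervals; or a GFF3 file, from which
#' the `exon` features of the requested gene are taken together with the CDS
#' span (first CDS base = ATG, last CDS base = stop end, in transcription
#' order).
#'
#' @param path File path.
#' @param gene_id Gene to select (required for GFF3 files containing more
#'   than one gene).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, gene_id = NULL) {
  first <- readLines(path, n = 50L)
  if (any(startsWith(first, "##gff")) || grepl("\tgene\t|\texon\t|\tCDS\t", paste(first, collapse = "\n"))) {
    return(read_gene_model_gff3(path, gene_id))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(gene_id)) df <- df[df$gene_id == gene_id, , drop = FALSE]
  if (nrow(df) != 1L) stop("expected exactly one gene-model row, got ", nrow(df))
  ex <- do.call(rbind, lapply(strsplit(df$exons, ",")[[1]], function(iv) {
    as.integer(strsplit(iv, "-", fixed = TRUE)[[1]])
  }))
  gene_model(df$gene_id, df$seq_id, df$strand, df$atg_pos, df$stop_end, ex)
}

read_gene_model_gff3 <- function(path, gene_id = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stop("malformed GFF3 line(s): ", which(bad)[1])
  g <- data.frame(
    seqid = vapply(f, `[`, "", 1L), type = vapply(f, `[`, "", 3L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L), attr = vapply(f, `[`, "", 9L),
    stringsAsFactors = FALSE
  )
  attr_field <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  g$gene <- attr_field(g$attr, "ID")
  parent <- attr_field(g$attr, "Parent")
  g$gene[is.na(g$gene)] <- parent[is.na(g$gene)]
  # strip transcript suffixes like ".1"
  root <- sub("\\.\\d+$", "", g$gene)
  ids <- unique(root[g$type == "gene"])
  if (!length(ids)) ids <- unique(root)
  if (is.null(gene_id)) {
    if (length(ids) != 1L) stop("gene_id required; file contains: ",
                                paste(ids, collapse = ", "))
    gene_id <- ids
  }
  sel <- root == gene_id
  ex <- g[sel & g$type == "exon", , drop = FALSE]
  cds <- g[sel & g$type == "CDS", , drop = FALSE]
  if (!nrow(ex) || !nrow(cds)) stop("gene ", gene_id, " needs exon and CDS features")
  strand <- unique(c(ex$strand, cds$strand))
  if (length(strand) != 1L) stop("inconsistent strand for ", gene_id)
  if (strand == "+") {
    atg <- min(cds$start); stop_end <- max(cds$end)
  } else {
    atg <- max(cds$end); stop_end <- min(cds$start)
  }
  gene_model(gene_id, unique(ex$seqid)[1], strand, atg, stop_end,
             cbind(ex$start, ex$end))
}

#' Read a panel FASTA into a named sequence vector
#'
#' @param path FASTA file; record ids must be unique.
#' @return Named character vector, accession -> uppercase DNA.
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) check_dna(seqs[[i]], paste0("record ", ids[i]))
  seqs
}

#' Write a panel of sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @export
write_panel_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a locus sequence
#'
#' An extracted, plus-oriented gene region: upstream flank + genic region +
#' downstream flank, with 0-based offsets of the ATG and the last stop-codon
#' base.
#'
#' @param accession Accession name.
#' @param gene_id Gene identifier.
#' @param seq DNA sequence.
#' @param atg_offset 0-based index of the A of ATG within `seq`.
#' @param stop_offset 0-based index of the last stop-codon base.
#' @param source_interval Optional `c(start, end)` genomic interval of origin.
#' @return An object of class `locus_seq`.
#' @export
locus_sequence <- function(accession, gene_id, seq, atg_offset, stop_offset,
                           source_interval = NULL) {
  seq <- check_dna(seq, "locus sequence")
  atg_offset <- as.integer(atg_offset); stop_offset <- as.integer(stop_offset)
  if (!(0L <= atg_offset && atg_offset < stop_offset &&
        stop_offset < nchar(seq))) {
    stop("require 0 <= atg_offset < stop_offset < length(seq)")
  }
  structure(
    list(accession = accession, gene_id = gene_id, seq = seq,
         atg_offset = atg_offset, stop_offset = stop_offset,
         source_interval = source_interval),
    class = "locus_seq"
  )
}

#' @export
print.locus_seq <- function(x, ...) {
  cat(sprintf("<locus_seq> %s / %s  %d bp (ATG at offset %d)\n",
              x$gene_id, x$accession, nchar(x$seq), x$atg_offset))
  invisible(x)
}

#' Extract the analysis region of a gene from a genomic sequence
#'
#' The analysis region is a fixed window: `upstream` bp 5' of the start codon
#' (2 kb by default), the genic region from ATG through the stop codon, and
#' `downstream` bp 3' of the stop codon (1 kb by default).  Minus-strand
#' genes are reverse-complemented so the returned locus is always
#' plus-oriented with `atg_offset = upstream`.
#'
#' Flanks that run off the contig are an error by default, because haplotype
#' comparability requires equal regions across accessions;
#' `allow_truncation = TRUE` downgrades this to a warning and records the
#' actual flank obtained.
#'
#' @param genome Genomic DNA of the model's `seq_id` (single string).
#' @param model A [gene_model()].
#' @param upstream,downstream Flank lengths in bp.
#' @param accession Accession label for the result.
#' @param allow_truncation Clip flanks at contig ends instead of erroring.
#' @return A [locus_sequence()].
#' @export
extract_locus <- function(genome, model, upstream = 2000L, downstream = 1000L,
                          accession = "genome", allow_truncation = FALSE) {
  genome <- check_dna(genome, "genome")
  n <- nchar(genome)
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (model$strand == "+") {
    lo <- model$atg_pos - upstream
    hi <- model$stop_end + downstream
  } else {
    lo <- model$stop_end - downstream
    hi <- model$atg_pos + upstream
  }
  trunc5 <- max(0L, 1L - lo)   # bases missing on the genomic left
  trunc3 <- max(0L, hi - n)
  if ((trunc5 > 0L || trunc3 > 0L)) {
    side <- c(if (trunc5 > 0L) "5' (left)", if (trunc3 > 0L) "3' (right)")
    msg <- paste0("flank runs off the contig on the ", paste(side, collapse = " and "),
                  " side for ", model$gene_id)
    if (!allow_truncation) stop(msg) else warning(msg, "; flank truncated")
    lo <- max(1L, lo); hi <- min(n, hi)
  }
  seq <- substr(genome, lo, hi)
  genic_len <- abs(model$stop_end - model$atg_pos) + 1L
  if (model$strand == "+") {
    atg_off <- upstream - trunc5
  } else {
    seq <- revcomp(seq)
    atg_off <- upstream - trunc3
  }
  locus_sequence(accession, model$gene_id, seq,
                 atg_off, atg_off + genic_len - 1L,
                 source_interval = c(lo, hi))
}

#' Read a restriction-enzyme catalog
#'
#' Flat TSV with columns `name`, `recognition` (IUPAC), `cut_offset`
#' (top-strand cut, bases from the recognition 5' end).  Lines starting with
#' `#` are comments.
#'
#' @param path Catalog file; defaults to the catalog bundled with the
#'   package (three assay enzymes plus ~40 common commercial enzymes).
#' @return An object of class `enzyme_catalog`: a list of [rest_enzyme()]
#'   in catalog (preference) order.
#' @export
read_enzyme_catalog <- function(path = system.file("extdata", "enzymes.tsv",
                                                   package = "haplomark")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(df))) {
    stop("enzyme catalog needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate enzyme name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    rest_enzyme(df$name[i], df$recognition[i], df$cut_offset[i])
  })
  names(entries) <- df$name
  structure(list(entries = entries, source = path), class = "enzyme_catalog")
}

#' @export
print.enzyme_catalog <- function(x, ...) {
  cat(sprintf("<enzyme_catalog> %d enzymes (%s)\n", length(x$entries),
              x$source))
  invisible(x)
}

#' Look up one enzyme in a catalog
#'
#' @param catalog An `enzyme_catalog`.
#' @param name Enzyme name.
#' @return A [rest_enzyme()].
#' @export
catalog_enzyme <- function(catalog, name) {
  e <- catalog$entries[[name]]
  if (is.null(e)) stop("enzyme not in catalog: ", name)
  e
}
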