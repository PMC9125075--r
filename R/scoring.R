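# Panel scoring: per-accession elite-haplotype counts, per-gene per-group
# elite frequencies, and marker-call to haplotype-call resolution.

#' Elite-haplotype map
#'
#' Which haplotype name(s) count as elite for each gene.  The default map is
#' read from the bundled file: HapB for every gene, plus HapC for ARE1.
#' Whether SBM1 HapD (a start-codon-disrupting type plausibly stronger than
#' HapB) should count is unresolved in the source survey; it is excluded by
#' default and included via `include_sbm1_hapd = TRUE`.
#'
#' @param path TSV with columns `gene` and `elite_haplotypes`
#'   (comma-separated names).
#' @param include_sbm1_hapd Also count SBM1 HapD as elite.
#' @return Named list, gene -> character vector of elite haplotype names.
#' @export
elite_map <- function(path = system.file("extdata", "elite_map.tsv",
                                         package = "haplomark"),
                      include_sbm1_hapd = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  em <- lapply(stats::setNames(df$elite_haplotypes, df$gene), function(s) {
    trimws(strsplit(s, ",")[[1]])
  })
  if (any(!lengths(em))) stop("every gene needs at least one elite haplotype")
  if (include_sbm1_hapd && "SBM1" %in% names(em)) {
    em$SBM1 <- union(em$SBM1, "HapD")
  }
  em
}

#' Count elite haplotypes in one accession's calls
#'
#' @param calls Named character vector, gene -> haplotype name or `"n.d."`.
#'   n.d. and missing calls contribute 0.
#' @param elite An [elite_map()].
#' @return Integer count.
#' @export
count_elite <- function(calls, elite) {
  genes <- names(calls)
  unknown <- setdiff(genes, names(elite))
  if (length(unknown)) {
    stop("gene(s) absent from the elite map: ", paste(unknown, collapse = ", "))
  }
  sum(vapply(genes, function(g) {
    !is.na(calls[[g]]) && calls[[g]] %in% elite[[g]]
  }, TRUE))
}

#' Load the bundled 36-accession haplotype survey
#'
#' Returns the transcribed 36-accession x 14-gene haplotype matrix with its
#' printed elite-count column.  Bold (elite-printed) flags are kept in a
#' separate matrix; printed counts are kept alongside recomputed ones so
#' the survey's internal inconsistencies stay visible rather than being
#' silently corrected.
#'
#' @param path TSV in the bundled layout.
#' @return A list of class `haplotype_survey`: `calls` (accession x gene
#'   character matrix, `"n.d."` for undetermined), `bold` (logical matrix),
#'   `info` (data.frame: accession, origin, subpop, group, printed_count).
#' @export
read_haplotype_survey <- function(path = system.file("extdata",
                                                     "haplotype_survey.tsv",
                                                     package = "haplomark")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  meta_cols <- c("accession", "origin", "subpop", "printed_count")
  genes <- setdiff(names(df), meta_cols)
  raw <- as.matrix(df[, genes])
  rownames(raw) <- df$accession
  bold <- matrix(grepl("\\*$", raw), nrow = nrow(raw), dimnames = dimnames(raw))
  calls <- sub("\\*$", "", raw)
  info <- data.frame(
    accession = df$accession, origin = df$origin, subpop = df$subpop,
    group = subspecies_group(df$subpop),
    printed_count = as.integer(df$printed_count),
    stringsAsFactors = FALSE
  )
  structure(list(calls = calls, bold = bold, info = info),
            class = "haplotype_survey")
}

#' @export
print.haplotype_survey <- function(x, ...) {
  cat(sprintf("<haplotype_survey> %d accessions x %d genes\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Collapse subpopulation labels to subspecies groups
#'
#' `XI*` labels collapse to `XI`, `GJ*` to `GJ`; circum-aus/basmati and
#' other labels are kept as-is.  Group labels are input metadata, never
#' inferred from sequence.
#'
#' @param subpop Character vector of subpopulation labels.
#' @return Character vector of group labels.
#' @export
subspecies_group <- function(subpop) {
  ifelse(grepl("^XI", subpop), "XI",
         ifelse(grepl("^GJ", subpop), "GJ", subpop))
}

#' Score a panel: per-accession elite counts
#'
#' @param survey A `haplotype_survey` (or compatible list with `calls` and
#'   `info`).
#' @param elite An [elite_map()].
#' @return A data.frame of class `score_report`: accession, group,
#'   elite_count (recomputed), printed_count (when available), and
#'   `count_discrepant` flagging rows where the two disagree.
#' @export
score_panel <- function(survey, elite = elite_map()) {
  calls <- survey$calls
  counts <- vapply(rownames(calls), function(a) {
    count_elite(stats::setNames(calls[a, ], colnames(calls)), elite)
  }, 0L)
  out <- data.frame(
    accession = rownames(calls),
    group = survey$info$group[match(rownames(calls), survey$info$accession)],
    elite_count = counts,
    stringsAsFactors = FALSE
  )
  if ("printed_count" %in% names(survey$info)) {
    out$printed_count <- survey$info$printed_count[
      match(out$accession, survey$info$accession)]
    out$count_discrepant <- !is.na(out$printed_count) &
      out$printed_count != out$elite_count
  }
  class(out) <- c("score_report", class(out))
  out
}

#' Summarize elite-haplotype distribution by group
#'
#' Per gene and group: how many accessions carry an elite haplotype; plus
#' per-group min/max/mean of the per-accession elite counts.  Empty groups
#' yield zero rows without division by zero.
#'
#' @param survey A `haplotype_survey`.
#' @param elite An [elite_map()].
#' @return A list: `per_gene` (data.frame gene x group carrier counts and
#'   frequencies) and `per_group` (data.frame group, n, min, max, mean of
#'   elite counts).
#' @export
summarize_by_group <- function(survey, elite = elite_map()) {
  calls <- survey$calls
  groups <- survey$info$group[match(rownames(calls), survey$info$accession)]
  glev <- unique(groups)
  per_gene <- do.call(rbind, lapply(colnames(calls), function(g) {
    do.call(rbind, lapply(glev, function(grp) {
      in_grp <- groups == grp
      det <- calls[in_grp, g] != "n.d."
      carriers <- sum(calls[in_grp, g] %in% elite[[g]])
      data.frame(gene = g, group = grp, n = sum(in_grp),
                 n_determined = sum(det), elite_carriers = carriers,
                 frequency = if (sum(in_grp)) carriers / sum(in_grp) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  scores <- score_panel(survey, elite)
  per_group <- do.call(rbind, lapply(glev, function(grp) {
    v <- scores$elite_count[scores$group == grp]
    data.frame(group = grp, n = length(v),
               min = if (length(v)) min(v) else 0L,
               max = if (length(v)) max(v) else 0L,
               mean = if (length(v)) mean(v) else 0,
               stringsAsFactors = FALSE)
  }))
  list(per_gene = per_gene, per_group = per_group)
}

#' Resolve marker band calls into a per-gene haplotype call
#'
#' Markers only resolve the classes they address, so non-target results are
#' reported as `"non-elite"` rather than inventing haplotype names.  When a
#' gene has two markers, their calls are resolved jointly: the haplotype
#' targeted by both, by one, or by neither, in the order the `rules` list
#' specifies; conflicting or null/ambiguous calls give `"n.d."`.
#'
#' @param band_calls Named character vector, marker name -> call
#'   (`ref_class`/`alt_class`/`ambiguous`/`null`).
#' @param markers List of [marker_assay()] for one gene.
#' @param rules Optional named list mapping a call signature to a haplotype
#'   label: names are comma-separated `alt`/`ref` flags in marker order
#'   (e.g. `"alt,alt" = "HapB"`, `"alt,ref" = "HapD"`).  When `NULL`, a
#'   single-marker gene maps alt to its (first) target haplotype and a
#'   two-marker gene maps via target-set intersection/difference.
#' @return Haplotype label, `"non-elite"`, or `"n.d."` (with attribute
#'   `conflict = TRUE` when two markers disagree irreconcilably).
#' @export
genotype_to_haplotype <- function(band_calls, markers, rules = NULL) {
  mk_names <- vapply(markers, `[[`, "", "name")
  calls <- band_calls[mk_names]
  if (all(calls %in% c("null", "ambiguous") | is.na(calls))) {
    return("n.d.")
  }
  if (any(calls %in% c("null", "ambiguous") | is.na(calls))) {
    # partially failed assays cannot resolve the class reliably
    return(structure("n.d.", conflict = TRUE))
  }
  sig <- paste(ifelse(calls == "alt_class", "alt", "ref"), collapse = ",")
  if (!is.null(rules)) {
    return(rules[[sig]] %||% "n.d.")
  }
  if (length(markers) == 1L) {
    if (calls == "alt_class") return(markers[[1L]]$target_haplotypes[1L])
    return("non-elite")
  }
  targets <- lapply(markers, `[[`, "target_haplotypes")
  flags <- calls == "alt_class"
  if (!any(flags)) return("non-elite")
  hit <- Reduce(intersect, targets[flags])
  hit <- setdiff(hit, unlist(targets[!flags]))
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L) return(paste(sort(hit), collapse = "/"))
  structure("n.d.", conflict = TRUE)
}

#' Load an external panel score table
#'
#' Reader for external survey-shaped panels (accession, group, one column per
#' gene, calls as haplotype names or `n.d.`): survey tables for panels not
#' bundled with the package become one-command checks when such a file is
#' supplied.
#'
#' @param path TSV with columns `accession`, `subpop` (or `group`), then one
#'   column per gene.
#' @return A `haplotype_survey` (without bold flags or printed counts).
#' @export
read_panel_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (!"accession" %in% names(df)) stop("panel table needs an accession column")
  grp_col <- intersect(c("group", "subpop"), names(df))[1]
  if (is.na(grp_col)) stop("panel table needs a group or subpop column")
  meta <- c("accession", "origin", "subpop", "group", "printed_count")
  genes <- setdiff(names(df), meta)
  calls <- as.matrix(df[, genes, drop = FALSE])
  rownames(calls) <- df$accession
  info <- data.frame(
    accession = df$accession,
    origin = if ("origin" %in% names(df)) df$origin else NA_character_,
    subpop = df[[grp_col]], group = subspecies_group(df[[grp_col]]),
    stringsAsFactors = FALSE
  )
  if ("printed_count" %in% names(df)) {
    info$printed_count <- as.integer(df$printed_count)
  }
  structure(list(calls = calls, bold = NULL, info = info),
            class = "haplotype_survey")
}
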