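# Grouping accessions into named haplotypes from a variant matrix.
# Naming convention: the reference accession's profile is HapA; the
# designated elite profile is HapB; remaining haplotypes are named HapC,
# HapD, ... by descending member count, ties broken by the alphabetically
# first member accession.  Panel accessions are assumed to be inbred lines
# (homozygous); heterozygous genotypes are an input error.

#' Build a variant matrix for a panel
#'
#' Aligns every accession's locus to the reference, calls variants, and
#' assembles the accession-by-variant genotype table (`"ref"`/`"alt"`;
#' `"missing"` for accessions absent from the panel).
#'
#' @param panel Named list of [locus_sequence()] objects (or a named DNA
#'   character vector, in which case `ref_locus`'s offsets are reused after
#'   alignment).
#' @param ref_locus The reference accession's [locus_sequence()].
#' @param model Optional [gene_model()] for region annotation.
#' @param scoring [align_params()].
#' @return A list of class `variant_matrix`: `variants` (data.frame, one row
#'   per distinct variant), `genotypes` (accession x variant character
#'   matrix), `ref_accession`, and `per_accession` (list of per-accession
#'   variant ids).
#' @export
build_variant_matrix <- function(panel, ref_locus, model = NULL,
                                 scoring = align_params()) {
  stopifnot(inherits(ref_locus, "locus_seq"))
  if (is.character(panel)) {
    panel <- lapply(stats::setNames(names(panel), names(panel)), function(a) {
      locus_sequence(a, ref_locus$gene_id, panel[[a]],
                     ref_locus$atg_offset, ref_locus$stop_offset)
    })
  }
  accs <- names(panel)
  per_acc <- list()
  all_variants <- list()
  for (a in accs) {
    if (identical(a, ref_locus$accession)) {
      per_acc[[a]] <- character(0)
      next
    }
    aln <- align_to_reference(panel[[a]], ref_locus, scoring)
    v <- call_variants(aln, model)
    ids <- if (nrow(v)) variant_id(v) else character(0)
    per_acc[[a]] <- ids
    if (nrow(v)) {
      v$id <- ids
      all_variants[[a]] <- v
    }
  }
  if (!(ref_locus$accession %in% accs)) {
    per_acc[[ref_locus$accession]] <- character(0)
    accs <- c(ref_locus$accession, accs)
  }
  variants <- if (length(all_variants)) {
    vv <- do.call(rbind, all_variants)
    vv <- vv[!duplicated(vv$id), , drop = FALSE]
    vv[order(abs(vv$position), sign(vv$position)), , drop = FALSE]
  } else {
    v0 <- cbind(variant(1, "SNP", "A", "A")[0, ], has_n = logical(0))
    v0$id <- character(0)
    v0
  }
  rownames(variants) <- NULL
  geno <- matrix("ref", nrow = length(accs), ncol = nrow(variants),
                 dimnames = list(accs, variants$id))
  for (a in names(per_acc)) geno[a, colnames(geno) %in% per_acc[[a]]] <- "alt"
  structure(
    list(variants = variants, genotypes = geno,
         ref_accession = ref_locus$accession, per_accession = per_acc),
    class = "variant_matrix"
  )
}

#' Construct a variant matrix directly from genotype calls
#'
#' Entry point for pre-computed variant tables (e.g. loci whose structural
#' variants exceed the alignment size bound).
#'
#' @param variants Data.frame with at least `position`, `vtype`,
#'   `ref_allele`, `alt_allele` (an `id` column is derived).
#' @param genotypes Accession x variant character matrix of
#'   `"ref"`/`"alt"`/`"missing"`; column order must match `variants` rows.
#' @param ref_accession Name of the reference accession (must be a row).
#' @return A `variant_matrix`.
#' @export
variant_matrix <- function(variants, genotypes, ref_accession) {
  if (!"id" %in% names(variants)) variants$id <- variant_id(variants)
  stopifnot(ncol(genotypes) == nrow(variants))
  colnames(genotypes) <- variants$id
  if (!ref_accession %in% rownames(genotypes)) {
    stop("ref_accession not in genotype rows: ", ref_accession)
  }
  bad <- !genotypes %in% c("ref", "alt", "missing")
  if (any(bad)) {
    stop("genotypes must be ref/alt/missing (inbred panel; no heterozygotes)")
  }
  structure(
    list(variants = variants, genotypes = genotypes,
         ref_accession = ref_accession,
         per_accession = apply(genotypes, 1L, function(r) {
           colnames(genotypes)[r == "alt"]
         }, simplify = FALSE)),
    class = "variant_matrix"
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d accessions x %d variants (ref: %s)\n",
              nrow(x$genotypes), nrow(x$variants), x$ref_accession))
  invisible(x)
}

#' Group accessions into named haplotypes
#'
#' Accessions with identical genotype rows share a haplotype.  The reference
#' accession's haplotype is HapA; the haplotype whose profile equals
#' `elite_profile` is HapB; remaining haplotypes are HapC, HapD, ... by
#' descending member count (ties: alphabetically first member).  When no
#' accession carries the elite profile, HapB is reserved but empty and a
#' warning is emitted.
#'
#' @param matrix A `variant_matrix`.
#' @param ref_accession Reference accession (defaults to the matrix's).
#' @param elite_profile Optional character vector of variant ids (the
#'   alt-allele subset defining the elite haplotype).
#' @param exclude Accessions to leave out of grouping (e.g. n.d. accessions).
#' @return A list of class `haplotype_set`: `gene_id`-free named list
#'   `haplotypes` of `(name, profile, members)`, plus `nd_accessions` and
#'   `elite_names`.
#' @export
group_haplotypes <- function(matrix, ref_accession = matrix$ref_accession,
                             elite_profile = NULL, exclude = character(0)) {
  stopifnot(inherits(matrix, "variant_matrix"))
  geno <- matrix$genotypes
  if (!ref_accession %in% rownames(geno)) {
    stop("reference accession not in matrix: ", ref_accession)
  }
  accs <- setdiff(rownames(geno), exclude)
  profiles <- lapply(stats::setNames(accs, accs), function(a) {
    sort(colnames(geno)[geno[a, ] == "alt"])
  })
  # "#"-prefixed so the empty (reference) profile is a usable list name
  key <- vapply(profiles, function(p) paste0("#", paste(p, collapse = "|")), "")
  groups <- split(accs, key[accs])
  # order groups for naming
  grp_profile <- lapply(groups, function(m) profiles[[m[1]]])
  ref_key <- key[[ref_accession]]
  elite_key <- if (!is.null(elite_profile)) {
    paste0("#", paste(sort(elite_profile), collapse = "|"))
  } else NULL
  rest <- setdiff(names(groups), c(ref_key, elite_key))
  sizes <- vapply(groups[rest], length, 0L)
  first_member <- vapply(groups[rest], function(m) sort(m)[1], "")
  rest <- rest[order(-sizes, first_member)]
  ordered_keys <- c(ref_key,
                    if (!is.null(elite_key)) elite_key,
                    rest)
  haps <- list()
  next_letter <- 1L
  for (k in ordered_keys) {
    nm <- paste0("Hap", LETTERS[next_letter])
    next_letter <- next_letter + 1L
    members <- if (k %in% names(groups)) sort(groups[[k]]) else character(0)
    prof <- if (k %in% names(groups)) grp_profile[[k]] else
      strsplit(sub("^#", "", k), "|", fixed = TRUE)[[1]]
    haps[[nm]] <- list(name = nm, profile = prof, members = members)
  }
  elite_names <- if (!is.null(elite_key)) "HapB" else character(0)
  if (!is.null(elite_key) && !length(haps[["HapB"]]$members)) {
    warning("elite profile matches no accession; HapB reserved but empty")
  }
  structure(
    list(gene_id = attr(matrix, "gene_id"), haplotypes = haps,
         nd_accessions = exclude, elite_names = elite_names),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set>\n")
  for (h in x$haplotypes) {
    cat(sprintf("  %s%s: %d member(s), %d variant(s)\n", h$name,
                if (h$name %in% x$elite_names) "*" else "",
                length(h$members), length(h$profile)))
  }
  if (length(x$nd_accessions)) {
    cat("  n.d.:", paste(x$nd_accessions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Membership lookup in a haplotype set
#'
#' @param haps A `haplotype_set`.
#' @return Named character vector accession -> haplotype name (`"n.d."` for
#'   undetermined accessions).
#' @export
haplotype_assignments <- function(haps) {
  out <- c()
  for (h in haps$haplotypes) {
    out[h$members] <- h$name
  }
  out[haps$nd_accessions] <- "n.d."
  out
}

#' Flag an accession as not-determined (n.d.)
#'
#' An accession is n.d. when its gene sequence could not be extracted
#' (absent from the matrix), or when it carries more than `novel_threshold`
#' alt alleles found in no named haplotype profile ("many novel
#' variations").
#'
#' @param accession Accession name.
#' @param matrix A `variant_matrix`.
#' @param haps Optional `haplotype_set` providing the named profiles; when
#'   absent, any alt allele carried by another accession counts as part of a
#'   named profile (so "novel" means private to this accession).
#' @param novel_threshold Count above which novel variants trigger n.d.
#' @return Logical.
#' @export
flag_nd <- function(accession, matrix, haps = NULL, novel_threshold = 5L) {
  stopifnot(inherits(matrix, "variant_matrix"))
  geno <- matrix$genotypes
  if (!accession %in% rownames(geno)) return(TRUE)
  if (any(geno[accession, ] == "missing")) return(TRUE)
  own <- colnames(geno)[geno[accession, ] == "alt"]
  if (!is.null(haps)) {
    named <- unique(unlist(lapply(haps$haplotypes, `[[`, "profile")))
  } else {
    others <- setdiff(rownames(geno), accession)
    prof <- lapply(others, function(a) colnames(geno)[geno[a, ] == "alt"])
    named <- unique(unlist(prof))
  }
  sum(!(own %in% named)) > novel_threshold
}

#' Classify a panel into haplotypes with the n.d. rule applied
#'
#' Convenience wrapper: groups all accessions, flags accessions carrying
#' more than `novel_threshold` private variants as n.d., and regroups the
#' remainder.
#'
#' @inheritParams group_haplotypes
#' @param novel_threshold Passed to [flag_nd()].
#' @return A `haplotype_set`.
#' @export
classify_haplotypes <- function(matrix, ref_accession = matrix$ref_accession,
                                elite_profile = NULL, novel_threshold = 5L) {
  accs <- rownames(matrix$genotypes)
  nd <- accs[vapply(accs, function(a) {
    a != ref_accession && flag_nd(a, matrix, novel_threshold = novel_threshold)
  }, TRUE)]
  group_haplotypes(matrix, ref_accession, elite_profile, exclude = nd)
}
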