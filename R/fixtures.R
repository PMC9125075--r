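# Synthetic panels with planted haplotypes, and templates synthesized from a
# marker's own specification.  The generator emulates panels of inbred
# (homozygous) accessions over a 3-10 kb gene locus: a random reference
# sequence with a canonical ATG and stop codon, haplotype profiles planted
# as SNP/indel edits, and a truth table for every downstream stage.  It does
# not simulate sequencing reads, base-call errors or alignment artifacts.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specify a synthetic panel
#'
#' @param seed Integer seed; all generation is deterministic given it.
#' @param upstream,downstream Flank lengths around the genic region.
#' @param exon_lengths,intron_lengths Genic structure in bp
#'   (`length(intron_lengths) == length(exon_lengths) - 1`).
#' @param profiles Named list of haplotype profiles.  Each profile is a list
#'   of planted variants `list(position =, vtype =, len =, alt =)`:
#'   `position` is ATG-relative (no zero), `vtype` one of SNP/INS/DEL,
#'   `len` the indel length (`alt` optionally a concrete SNP/insertion
#'   allele).  The reference profile must be an empty list named `"HapA"`.
#' @param assignment Named character vector accession -> profile name; must
#'   assign at least one accession (the reference) to `"HapA"`.
#' @param ref_accession Name of the reference accession.
#' @param gc GC fraction of the generated locus.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(seed, upstream = 2000L, downstream = 1000L,
                       exon_lengths = c(400L, 300L, 500L),
                       intron_lengths = c(250L, 350L),
                       profiles = list(HapA = list()),
                       assignment = c(NIP = "HapA"),
                       ref_accession = names(assignment)[1L],
                       gc = 0.45) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L)
  if (!"HapA" %in% names(profiles) || length(profiles$HapA)) {
    stop("profiles must contain an empty reference profile named HapA")
  }
  if (!all(assignment %in% names(profiles))) {
    stop("assignment refers to unknown profile(s)")
  }
  if (!identical(unname(assignment[ref_accession]), "HapA")) {
    stop("the reference accession must carry HapA")
  }
  # indel-involving variant pairs need >= 20 bp of separation so calls are
  # unambiguous; SNP pairs may sit close together (dense haplotypes do)
  pv <- do.call(rbind, lapply(profiles, function(p) {
    if (!length(p)) return(NULL)
    data.frame(position = vapply(p, `[[`, 0, "position"),
               vtype = vapply(p, `[[`, "", "vtype"))
  }))
  if (!is.null(pv) && nrow(pv) > 1L) {
    pv <- pv[!duplicated(pv$position), , drop = FALSE]
    pv <- pv[order(pv$position), , drop = FALSE]
    close_pair <- diff(pv$position) < 20L
    indel_pair <- pv$vtype[-nrow(pv)] != "SNP" | pv$vtype[-1L] != "SNP"
    if (any(close_pair & indel_pair)) {
      stop("indel-involving planted variants closer than 20 bp")
    }
    if (any(diff(pv$position) < 2L)) stop("planted variants overlap")
  }
  if (!is.null(pv) && any(pv$position == 0L)) stop("position 0 is not defined")
  structure(
    list(seed = as.integer(seed), upstream = as.integer(upstream),
         downstream = as.integer(downstream),
         exon_lengths = as.integer(exon_lengths),
         intron_lengths = as.integer(intron_lengths),
         profiles = profiles, assignment = assignment,
         ref_accession = ref_accession, gc = gc),
    class = "panel_spec"
  )
}

#' Generate a synthetic panel with planted haplotypes
#'
#' Deterministic under the spec's seed.  The reference accession carries no
#' alt allele; every other accession's sequence embodies exactly its
#' profile.  Local sequence context around planted indels is adjusted so
#' that each indel is already left-aligned (the planted coordinates are the
#' normalized ones the caller can compare against).
#'
#' @param spec A [panel_spec()].
#' @return A list of class `synthetic_panel`: `panel` (named DNA vector),
#'   `ref_locus` ([locus_sequence()]), `model` ([gene_model()]),
#'   `truth_matrix` (`variant_matrix`), `truth_haps` (`haplotype_set`),
#'   `truth_variants` (data.frame with profile membership), and `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_local_seed(spec$seed, {
    genic_len <- sum(spec$exon_lengths) + sum(spec$intron_lengths)
    total <- spec$upstream + genic_len + spec$downstream
    ref <- rand_dna(total, spec$gc)
    atg0 <- spec$upstream                   # 0-based ATG offset
    substr(ref, atg0 + 1L, atg0 + 3L) <- "ATG"
    stop0 <- atg0 + genic_len - 1L          # 0-based last stop base
    substr(ref, stop0 - 1L, stop0 + 1L) <- "TAA"
    # gene model on the synthetic "contig" (the locus itself)
    atg_pos <- atg0 + 1L
    bounds <- integer(0)
    cur <- atg_pos
    ex <- matrix(0L, nrow = length(spec$exon_lengths), ncol = 2L)
    for (k in seq_along(spec$exon_lengths)) {
      ex[k, ] <- c(cur, cur + spec$exon_lengths[k] - 1L)
      cur <- ex[k, 2L] + 1L
      if (k <= length(spec$intron_lengths)) cur <- cur + spec$intron_lengths[k]
    }
    model <- gene_model("synthgene", "synthctg", "+", atg_pos,
                        atg_pos + genic_len - 1L, ex)
    ref_locus <- locus_sequence(spec$ref_accession, "synthgene", ref,
                                atg0, stop0)
    # concretize planted variants against the reference and fix contexts so
    # indels are unambiguous (already left-aligned)
    planted <- list()
    for (hp in names(spec$profiles)) {
      for (v in spec$profiles[[hp]]) {
        key <- paste0(v$position, ":", v$vtype)
        if (!is.null(planted[[key]])) next
        planted[[key]] <- concretize_variant(v, ref_locus)
      }
    }
    # context fixes may mutate the reference; apply them
    for (p in planted) {
      if (!is.null(p$ctx_fix)) {
        substr(ref, p$ctx_fix$at, p$ctx_fix$at) <- p$ctx_fix$base
      }
    }
    ref_locus <- locus_sequence(spec$ref_accession, "synthgene", ref,
                                atg0, stop0)
    truth_variants <- do.call(rbind, lapply(planted, function(p) {
      v <- variant(p$position, p$vtype, p$ref_allele, p$alt_allele,
                   annotate_region(p$position, model))
      v$has_n <- FALSE
      v$id <- variant_id(v)
      v
    }))
    rownames(truth_variants) <- NULL
    # build each accession's sequence by applying its profile 3' -> 5'
    panel <- stats::setNames(character(length(spec$assignment)),
                             names(spec$assignment))
    for (acc in names(spec$assignment)) {
      hp <- spec$assignment[[acc]]
      keys <- vapply(spec$profiles[[hp]], function(v) {
        paste0(v$position, ":", v$vtype)
      }, "")
      edits <- planted[keys]
      ord <- order(-vapply(edits, `[[`, 0L, "off0"))
      seq <- ref
      for (p in edits[ord]) seq <- apply_edit(seq, p)
      panel[[acc]] <- seq
    }
    # truth matrix and haplotype set
    geno <- matrix("ref", nrow = length(panel), ncol = nrow(truth_variants),
                   dimnames = list(names(panel), truth_variants$id))
    prof_ids <- lapply(spec$profiles, function(pr) {
      vapply(pr, function(v) {
        planted[[paste0(v$position, ":", v$vtype)]]$id
      }, "")
    })
    for (acc in names(spec$assignment)) {
      geno[acc, colnames(geno) %in% prof_ids[[spec$assignment[[acc]]]]] <- "alt"
    }
    tm <- variant_matrix(truth_variants, geno, spec$ref_accession)
    haps <- lapply(names(spec$profiles), function(hp) {
      list(name = hp, profile = sort(prof_ids[[hp]]),
           members = sort(names(spec$assignment)[spec$assignment == hp]))
    })
    names(haps) <- names(spec$profiles)
    truth_haps <- structure(
      list(gene_id = "synthgene", haplotypes = haps,
           nd_accessions = character(0),
           elite_names = intersect("HapB", names(haps))),
      class = "haplotype_set"
    )
    structure(
      list(panel = panel, ref_locus = ref_locus, model = model,
           truth_matrix = tm, truth_haps = truth_haps,
           truth_variants = truth_variants, spec = spec),
      class = "synthetic_panel"
    )
  })
}

# Turn a profile entry into concrete alleles at a locus offset; returns the
# edit record plus an optional one-base reference fix that guarantees the
# indel is left-aligned as planted.
concretize_variant <- function(v, ref_locus) {
  off0 <- unlabel_position(v$position, ref_locus)
  ref <- ref_locus$seq
  bases <- c("A", "C", "G", "T")
  out <- list(position = v$position, vtype = v$vtype, off0 = off0)
  if (v$vtype == "SNP") {
    rb <- substr(ref, off0 + 1L, off0 + 1L)
    ab <- v$alt %||% sample(setdiff(bases, rb), 1L)
    if (ab == rb) stop("planted SNP alt equals the reference base")
    out$ref_allele <- rb; out$alt_allele <- ab
  } else if (v$vtype == "DEL") {
    L <- v$len
    seg <- substr(ref, off0 + 1L, off0 + L)
    prev_at <- off0            # 1-based position of the base 5' of the indel
    last <- substr(seg, L, L)
    if (prev_at >= 1L && substr(ref, prev_at, prev_at) == last) {
      out$ctx_fix <- list(at = prev_at, base = sample(setdiff(bases, last), 1L))
    }
    out$ref_allele <- seg; out$alt_allele <- "-"
  } else if (v$vtype == "INS") {
    L <- v$len
    ins <- v$alt %||% rand_dna(L, 0.5)
    prev_at <- off0
    prev <- if (prev_at >= 1L) substr(ref, prev_at, prev_at) else ""
    # avoid left-shift: the inserted segment's last base must differ from
    # the base 5' of the insertion point, and the segment must not equal
    # the reference bases it would sit after (repeat creation)
    if (nzchar(prev) && substr(ins, L, L) == prev) {
      substr(ins, L, L) <- sample(setdiff(bases, prev), 1L)
    }
    nxt <- substr(ref, off0 + 1L, off0 + 1L)
    if (substr(ins, 1L, 1L) == nxt && L > 1L) {
      # harmless, but avoid right-repeat for readability of truth tables
      substr(ins, 1L, 1L) <- sample(setdiff(bases, nxt), 1L)
    }
    if (nzchar(prev) && substr(ins, L, L) == prev) {
      substr(ins, L, L) <- sample(setdiff(bases, c(prev)), 1L)
    }
    out$ref_allele <- "-"; out$alt_allele <- ins
  } else {
    stop("unsupported planted vtype: ", v$vtype)
  }
  vv <- variant(out$position, out$vtype, out$ref_allele, out$alt_allele)
  out$id <- variant_id(vv)
  out
}

apply_edit <- function(seq, p) {
  off0 <- p$off0
  if (p$vtype == "SNP") {
    substr(seq, off0 + 1L, off0 + 1L) <- p$alt_allele
    seq
  } else if (p$vtype == "DEL") {
    paste0(substr(seq, 1L, off0), substr(seq, off0 + 1L + nchar(p$ref_allele),
                                         nchar(seq)))
  } else {
    paste0(substr(seq, 1L, off0), p$alt_allele,
           substr(seq, off0 + 1L, nchar(seq)))
  }
}

#' Draw a random panel specification
#'
#' Convenience generator for property tests: a random gene structure, a
#' random number of haplotype profiles with planted SNPs and 5-30 bp indels
#' spaced at least 20 bp apart, and a random accession assignment.
#'
#' @param seed Integer seed.
#' @param n_accessions Panel size (reference included).
#' @param n_haplotypes Number of distinct profiles (including HapA).
#' @param locus_kb Approximate genic+flank scale; the default draws loci of
#'   roughly 3-5 kb.
#' @return A [panel_spec()].
#' @export
random_panel_spec <- function(seed, n_accessions = 6L, n_haplotypes = 3L,
                              locus_kb = NULL) {
  with_local_seed(seed, {
    exn <- sample(2:5, 1L)
    exon_lengths <- sample(150:600, exn, replace = TRUE)
    intron_lengths <- sample(100:400, exn - 1L, replace = TRUE)
    upstream <- 1200L; downstream <- 600L
    genic <- sum(exon_lengths) + sum(intron_lengths)
    # candidate planted positions, >= 20 bp apart, away from ATG/stop/ends
    lo <- -(upstream - 60L); hi <- genic + downstream - 60L
    cand <- seq(lo, hi, by = 23L)
    cand <- cand[cand != 0L & abs(cand) > 5L & abs(cand - genic) > 5L]
    profiles <- list(HapA = list())
    used <- integer(0)
    for (h in seq_len(n_haplotypes - 1L)) {
      k <- sample(2:5, 1L)
      pos <- sample(setdiff(cand, used), k)
      used <- c(used, pos)
      profiles[[paste0("Hap", LETTERS[h + 1L])]] <- lapply(pos, function(p) {
        if (stats::runif(1) < 0.6) list(position = p, vtype = "SNP")
        else if (stats::runif(1) < 0.5) {
          list(position = p, vtype = "DEL", len = sample(5:18, 1L))
        } else {
          list(position = p, vtype = "INS", len = sample(5:18, 1L))
        }
      })
    }
    accs <- c("REF0", paste0("ACC", seq_len(n_accessions - 1L)))
    hps <- names(profiles)
    assignment <- stats::setNames(
      c("HapA", hps[1L + (seq_len(n_accessions - 1L) %% length(hps))]),
      accs
    )
    panel_spec(seed = seed, upstream = upstream, downstream = downstream,
               exon_lengths = exon_lengths, intron_lengths = intron_lengths,
               profiles = profiles, assignment = assignment,
               ref_accession = "REF0")
  })
}

#' Bundled transcribed marker set
#'
#' The 18 published assays (12 Indel, 3 CAPS, 1 dCAPS, 2 PARMS), parsed from
#' the transcription shipped with the package.
#'
#' @param catalog An `enzyme_catalog` for enzyme lookup.
#' @return List of [marker_assay()] objects.
#' @export
marker_table_fixture <- function(catalog = read_enzyme_catalog()) {
  read_marker_table(system.file("extdata", "marker_table.tsv",
                                package = "haplomark"), catalog)
}

#' Synthesize allele-class templates from a marker's own specification
#'
#' Builds a pair of template sequences (reference class and elite/alt class)
#' that are consistent with the assay's printed expectations: primer sites at
#' the implied spacing, the diagnostic indel, restriction site or SNP planted
#' between them, and no stray recognition sites elsewhere in the product.
#' This closes the design/assay loop for transcribed markers whose source
#' genomes are not available: it validates the assay engine against the
#' marker's specification, not against any real genome.
#'
#' @param marker A [marker_assay()].
#' @param cfg A [design_config()].
#' @param pad Extra template on each side of the amplicon.
#' @return A list `(ref, alt)` of DNA strings.
#' @export
synth_marker_template <- function(marker, cfg = design_config(), pad = 30L) {
  seed <- sum(utf8ToInt(marker$name))
  with_local_seed(seed, {
    switch(marker$mtype,
      Indel = synth_template_indel(marker, pad),
      CAPS = synth_template_caps(marker, pad),
      dCAPS = synth_template_dcaps(marker, pad),
      PARMS = synth_template_parms(marker, pad)
    )
  })
}

# random filler free of a given enzyme's sites in context
filler_avoiding <- function(n, enzyme = NULL, left = "", right = "") {
  f <- rand_dna(n, 0.45)
  if (is.null(enzyme)) return(f)
  for (i in 1:50) {
    ctx <- paste0(left, f, right)
    sites <- find_sites(ctx, enzyme)
    # only fix sites that overlap the filler region
    flo <- nchar(left) + 1L; fhi <- nchar(left) + n
    w <- nchar(enzyme$recognition)
    bad <- sites$start[sites$start + w >= flo & sites$start + 1L <= fhi]
    if (!length(bad)) return(f)
    for (s0 in bad) {
      at <- max(flo, min(fhi, s0 + 1L + sample.int(w, 1L) - 1L)) - nchar(left)
      old <- substr(f, at, at)
      substr(f, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  stop("could not generate enzyme-free filler")
}

synth_template_indel <- function(marker, pad) {
  fwd <- toupper(marker$primers$F); rev <- toupper(marker$primers$R)
  a_ref <- marker$expected$ref
  delta <- marker$expected$alt - a_ref
  fill_len <- a_ref - nchar(fwd) - nchar(rev)          # ref-class interior
  short_fill <- min(fill_len, fill_len + delta)        # interior of the
  stopifnot(short_fill >= 2L)                          # smaller class
  half <- short_fill %/% 2L
  left <- rand_dna(half); right <- rand_dna(short_fill - half)
  seg <- rand_dna(abs(delta))                          # the diagnostic indel
  if (delta < 0L) {          # elite class lacks `seg`
    core_ref <- paste0(left, seg, right); core_alt <- paste0(left, right)
  } else {                   # elite class carries `seg`
    core_ref <- paste0(left, right); core_alt <- paste0(left, seg, right)
  }
  p5 <- rand_dna(pad); p3 <- rand_dna(pad)
  list(ref = paste0(p5, fwd, core_ref, revcomp(rev), p3),
       alt = paste0(p5, fwd, core_alt, revcomp(rev), p3))
}

# concretize an IUPAC recognition into one matching concrete sequence
concrete_site <- function(recognition) {
  paste(vapply(strsplit(recognition, "", fixed = TRUE)[[1]], function(ch) {
    opts <- strsplit(IUPAC_CODES[[ch]], "", fixed = TRUE)[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

synth_template_caps <- function(marker, pad) {
  fwd <- toupper(marker$primers$F); rev <- toupper(marker$primers$R)
  enz <- marker$enzyme
  w <- nchar(enz$recognition)
  exp <- marker$expected
  cut_is_ref <- length(exp$ref) > 1L
  cut_frags <- if (cut_is_ref) exp$ref else exp$alt
  uncut_len <- if (cut_is_ref) exp$alt else exp$ref
  amp_len <- uncut_len[1L]                 # the uncut class fixes the length
  cutpos <- cut_frags[1L]                  # top-strand cut at this offset
  site0 <- cutpos - enz$cut_offset         # 0-based site start in amplicon
  site_seq <- concrete_site(enz$recognition)
  stopifnot(site0 >= nchar(fwd), site0 + w <= amp_len - nchar(rev))
  left_len <- site0 - nchar(fwd)
  right_len <- amp_len - nchar(rev) - site0 - w
  left <- filler_avoiding(left_len, enz, left = fwd, right = site_seq)
  right <- filler_avoiding(right_len, enz, left = site_seq,
                           right = revcomp(rev))
  cut_amp <- paste0(fwd, left, site_seq, right, revcomp(rev))
  # destroy the site in the other class by a single SNP at a concrete base
  rec_chars <- strsplit(enz$recognition, "", fixed = TRUE)[[1]]
  mutable <- which(vapply(rec_chars, function(ch) {
    nchar(IUPAC_CODES[[ch]]) < 4L
  }, TRUE))
  site_chars <- strsplit(site_seq, "", fixed = TRUE)[[1]]
  uncut_amp <- NULL
  for (at in mutable) {
    allowed <- strsplit(IUPAC_CODES[[rec_chars[at]]], "", fixed = TRUE)[[1]]
    for (b in setdiff(c("A", "C", "G", "T"), allowed)) {
      trial <- site_chars; trial[at] <- b
      cand <- paste0(fwd, left, paste(trial, collapse = ""), right,
                     revcomp(rev))
      if (length(digest(cand, enz)) == 1L) { uncut_amp <- cand; break }
    }
    if (!is.null(uncut_amp)) break
  }
  if (is.null(uncut_amp)) stop("could not destroy the diagnostic site")
  p5 <- filler_avoiding(pad, enz, right = substr(cut_amp, 1L, w))
  p3 <- filler_avoiding(pad, enz,
                        left = substr(cut_amp, nchar(cut_amp) - w + 1L,
                                      nchar(cut_amp)))
  if (cut_is_ref) {
    list(ref = paste0(p5, cut_amp, p3), alt = paste0(p5, uncut_amp, p3))
  } else {
    list(ref = paste0(p5, uncut_amp, p3), alt = paste0(p5, cut_amp, p3))
  }
}

synth_template_dcaps <- function(marker, pad) {
  fwd_marked <- marker$primers$F
  fwd <- toupper(fwd_marked); rev <- toupper(marker$primers$R)
  enz <- marker$enzyme
  w <- nchar(enz$recognition)
  exp <- marker$expected
  cut_is_ref <- length(exp$ref) > 1L
  uncut_len <- if (cut_is_ref) exp$alt else exp$ref
  amp_len <- uncut_len[1L]
  eng <- which(strsplit(fwd_marked, "", fixed = TRUE)[[1]] %in% letters)
  stopifnot(length(eng) >= 1L)
  # genomic template under the primer: engineered positions reverted to a
  # base that does not complete the site
  tmpl_primer_region <- fwd
  for (at in eng) {
    cur <- substr(fwd, at, at)
    repl <- setdiff(c("A", "C", "G", "T"), cur)[1L]
    substr(tmpl_primer_region, at, at) <- repl
  }
  fill_len <- amp_len - nchar(fwd) - nchar(rev)
  stopifnot(fill_len >= 1L)
  # SNP position: first template base after the primer
  base_rest <- filler_avoiding(fill_len - 1L, enz, left = fwd,
                               right = revcomp(rev))
  bases <- c("A", "C", "G", "T")
  cut_b <- uncut_b <- NULL
  for (b in bases) {
    prod <- paste0(fwd, b, base_rest, revcomp(rev))
    fr <- digest(prod, enz)
    genomic_ok <- length(digest(paste0(tmpl_primer_region, b, base_rest,
                                       revcomp(rev)), enz)) == 1L
    if (!genomic_ok) next
    if (length(fr) == 2L && is.null(cut_b)) cut_b <- b
    if (length(fr) == 1L && is.null(uncut_b)) uncut_b <- b
  }
  if (is.null(cut_b) || is.null(uncut_b)) {
    stop("could not plant a dCAPS-discriminating SNP for ", marker$name)
  }
  p5 <- filler_avoiding(pad, enz, right = substr(tmpl_primer_region, 1L, w))
  p3 <- filler_avoiding(pad, enz, left = substr(revcomp(rev),
                                                nchar(rev) - w + 1L,
                                                nchar(rev)))
  mk <- function(b) paste0(p5, tmpl_primer_region, b, base_rest,
                           revcomp(rev), p3)
  if (cut_is_ref) list(ref = mk(cut_b), alt = mk(uncut_b))
  else list(ref = mk(uncut_b), alt = mk(cut_b))
}

synth_template_parms <- function(marker, pad, amp_len = 160L) {
  cfg <- design_config()
  fc <- toupper(marker$primers$FC); ft <- toupper(marker$primers$FT)
  rev <- toupper(marker$primers$R)
  tail_len <- nchar(cfg$tail_fam)
  core_fc <- substr(fc, tail_len + 1L, nchar(fc))
  core_ft <- substr(ft, tail_len + 1L, nchar(ft))
  stopifnot(substr(core_fc, 1L, nchar(core_fc) - 1L) ==
              substr(core_ft, 1L, nchar(core_ft) - 1L))
  fill_len <- amp_len - nchar(core_fc) - nchar(rev)
  fill <- rand_dna(fill_len)
  p5 <- rand_dna(pad); p3 <- rand_dna(pad)
  list(ref = paste0(p5, core_fc, fill, revcomp(rev), p3),
       alt = paste0(p5, core_ft, fill, revcomp(rev), p3))
}
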