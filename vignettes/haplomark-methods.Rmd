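---
title: "From gene-region haplotypes to deployable markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gene-region haplotypes to deployable markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomark)
```

haplomark turns per-accession gene-region sequences into deployable
genotyping assays for marker-assisted selection. This vignette explains the
procedure the package implements, the assumptions behind it, the tunable
parameters and their defaults, and the places where the design was genuinely
open and a choice had to be made.

## The analysis region and its coordinates

Every analysis works on a fixed window around a gene: a 2-kb flank upstream
of the start codon, the genic region from the A of the ATG through the last
base of the stop codon (introns included), and a 1-kb downstream flank.
Following common usage in gene-based marker work, these flanks are labelled
5U and 3U even though they are fixed windows rather than transcript UTRs.
Minus-strand genes are reverse-complemented at extraction, so all downstream
logic sees a plus-oriented locus. Truncated flanks are an error by default
(`allow_truncation = TRUE` downgrades this to a warning): haplotype
comparability requires that every accession contributes the same region.

Positions are reported ATG-relative with no zero: +1 is the A of the ATG,
-1 the base immediately 5' of it. Positive positions run through introns
(so a position like +3326 can sit in the sixth intron). Genic positions map
to `E<k>`/`I<k>` region tags in transcription order; the marker-name region
code in names such as `NPF6.1 5U ID` or `SBM1 E3 S` comes from this
annotation. Where source material renders intron codes inconsistently
(e.g. "In6"), the package standardizes on `I<k>`.

## Variant calling and haplotype naming

Each accession's locus is aligned globally to the reference accession's
locus (Needleman–Wunsch with affine gaps, via Biostrings). The default
scoring — match +2, mismatch −3, gap open −5, gap extend −2 per base —
deliberately favors one long contiguous indel over fragmented gaps, which is
how structural variants in gene regions are conventionally described.
Alignment columns are reduced to variants as follows: isolated mismatch
columns become SNPs; maximal runs of gap columns become one insertion,
deletion, or (when both rows lose bases) one replacement (`SUB`). Indels are
left-aligned in repeat tracts and positioned at the first affected reference
base, following VCF community practice, so calls are deterministic and
comparable across accessions. Variants whose alleles contain `N` are
flagged and excluded from marker design.

The aligner refuses loci beyond about 20 kb; variants from such loci (for
example a multi-kb transposon insertion) enter through the variant-table
input path instead, where they are first-class rows like any called variant.

Accessions with identical genotype rows share a haplotype. The reference
accession's profile is HapA; the profile designated as elite is HapB; the
remaining haplotypes are named HapC, HapD, ... by descending member count,
ties broken by the alphabetically first member accession. The
frequency-then-lexicographic rule for the non-elite remainder is a package
convention: published surveys do not state how they ordered sub-haplotypes
that differ by a single SNP, and any fixed deterministic rule preserves the
partition, which is what downstream logic consumes. An accession is n.d.
(not determined) when its sequence cannot be extracted or when it carries
more than `novel_threshold` alt alleles found in no named profile; the
threshold defaults to 5, a concrete reading of "many novel variations" —
small enough to quarantine clearly divergent material, large enough that a
couple of private SNPs do not discard an accession.

Panel accessions are assumed to be inbred (homozygous) lines — germplasm
accessions and cultivars — so genotype states are `ref`/`alt`/`missing` and
heterozygous input is an error, not a model case.

## The design cascade

Diagnostic variants are those carried by every member of the target
haplotype(s) and by no member of any other named haplotype (n.d. accessions
are ignored). The cascade converts them into an assay in a fixed order of
preference:

1. **Indel marker** — an indel of 5–30 bp, typed by amplicon size on 4%
   polyacrylamide (PAGE); amplicon 100–300 bp.
2. **CAPS** — a SNP creating or destroying a catalog restriction site,
   typed by digestion fragments on 2% agarose; amplicon 100–500 bp.
3. **dCAPS** — a forward primer carrying one engineered mismatch completes
   a recognition site for exactly one allele; amplicon 100–300 bp, PAGE.
4. **PARMS** — penta-primer allele-specific PCR: two universal-tailed
   forward primers differing only in tail and 3'-terminal base, one common
   reverse primer, read by fluorophore.

The first success wins and the assay records which rule fired. Indels whose
size violates the 5–30 bp rule can still be emitted as structural-variant
markers (`allow_structural_override`, on by default, with a warning and
relaxed amplicon bounds): large replacements are perfectly typeable by
amplicon size even though they break the nominal rule, and published marker
sets contain such assays (a 1085-bp amplicon losing 615 bp, for instance).

Amplicons are additionally placed so they span no *other* segregating
variant at the locus. Without this constraint a second indel inside the
amplicon shifts part of the panel's products away from both expected
classes; passing the full variant table as `avoid_variants` is therefore
recommended whenever the cascade runs on real panels.

Primer placement is deterministic: smallest amplicon first, then the pair
with the highest minimum Tm, then the leftmost forward primer. Per-primer
constraints: length 18–24 nt, Tm 52–62 °C, GC 35–65%, no mononucleotide run
longer than 4, and no 4-bp 3'-end complementarity between partners. Tm uses
the nearest-neighbor model with the unified duplex parameters at 50 mM Na+
and 0.25 µM primer (entropy salt correction), with the Wallace
`2(A+T)+4(G+C)` rule below 14 nt; the implementation was checked against an
independent reference implementation to three decimals. Primer uniqueness
is checked only within the locus, not genome-wide — there is no genome
index here, and intragenic markers are expected to be locus-specific by
construction; this is a documented limitation.

dCAPS engineering follows standard practice: the mismatch sits at primer
positions 2–6 from the 3' end (never the terminal base, which must anchor
extension), at most one engineered mismatch by default, and the search is
exhaustive over primer ends within `len(recognition) − 1` bases of the SNP,
mismatch positions, and substitution bases, in a fixed order so results are
reproducible. On small contexts the search is verified against brute-force
enumeration in the test suite.

The bundled enzyme catalog holds the three assay enzymes used by the
transcribed marker set (TaqI, DdeI, and BglI — a printed catalog renders
the last ambiguously as "BgI I"; it is interpreted as BglI,
`GCCNNNN^NGGC`, and user catalogs are never silently rewritten) plus about
forty common commercial enzymes. Catalog order is preference order
(frequent, inexpensive cutters first); only top-strand cut positions are
modeled, because gel read-outs see fragment sizes, not overhang geometry.
Methylation sensitivity, star activity and partial digestion are out of
scope.

By convention the FAM-tailed PARMS primer (`FC`) carries the reference
allele and the HEX-tailed primer (`FT`) the alternate; swapping the tails
swaps the fluorophore classes but never the accession partition, and the
package tests that property.

## The in-silico assay

Virtual PCR uses a deliberately simple binding model rather than duplex
thermodynamics: a primer binds where its 3'-terminal base matches exactly
and at most one mismatch occurs within its 3'-most 20 bases; 5' overhangs
beyond that anchor dangle freely. This single rule reproduces the three
behaviors the assays depend on — engineered dCAPS mismatches still bind,
universal PARMS tails do not block amplification, and a 3'-terminal
mismatch is refractory, which is exactly what gives PARMS its allele
specificity. Products incorporate the primer sequences, as in a real
reaction, so engineered bases appear in the amplicon and are seen by the
digestion step. All binding parameters are exposed in `design_config()`.

Gel read-outs are compared at a resolution threshold: two fragments are
distinguishable iff they differ by at least 4 bp on PAGE (Indel and dCAPS
assays) or 20 bp on agarose (CAPS). The published gel recipes imply but do
not state resolutions; these thresholds are configuration, not constants.
This same rule is used when simulated patterns are compared with a marker
table's printed expectations — necessarily so, because printed gel sizes
are nominal: one transcribed CAPS encoding has fragments that do not sum to
its amplicon (320 vs 100+210), and the transcribed dCAPS primer's DdeI site
physically cuts 17 bp from the product end while the table prints the
fragment as 20 bp. Both agree with the simulation within gel resolution,
and the package reports the physically computed sizes rather than adjusting
them toward the printed ones.

`validate_marker` runs the assay over a panel with known haplotype truth:
target-haplotype members must call `alt_class`, all other named accessions
`ref_class`; n.d. accessions are exempt (a no-band accession is scored
n.d. for that gene, since published practice for null alleles downstream is
not stated). A marker whose two expected class patterns fall within gel
resolution fails as "unresolvable" regardless of concordance.

## Scoring panels

`count_elite` counts, per accession, the genes whose haplotype call is in
the elite map; n.d. never counts. The default map is HapB for every gene
plus HapC for ARE1 (its large 5' insertion plausibly lowers expression,
making it a second elite class); whether SBM1 HapD should count is
unresolved in the source survey — the marker set deliberately targets it,
but the survey does not flag it elite — so it is excluded by default behind
an explicit `include_sbm1_hapd` toggle. Marker-based haplotyping can only
resolve the classes the markers address, so non-target results are reported
as `"non-elite"` rather than inventing haplotype names; paired markers
(a CAPS targeting a haplotype family plus an Indel splitting it) are
resolved jointly by target-set intersection.

The bundled 36-accession survey stores the printed elite-count column
*alongside* the recomputed one. Recomputing from the matrix agrees with the
printed column for 33 of 36 rows; three rows (HZ, 9311, Y58S) each print
one fewer than their own bolded entries. The package flags these rather
than correcting either side, and treats the haplotype matrix as ground
truth. Group labels (XI, GJ, circum-aus/basmati) are input metadata, never
inferred from sequence.

The whole-collection figures that include unsequenced panels (a 55-XI mean
elite count, cultivar frequencies of individual alleles) cannot be
recomputed from the bundled survey, which covers only the 25 sequenced XI
accessions; `read_panel_table()` loads an external survey-shaped TSV so
those become one-command checks when such a table is available.

## The synthetic-panel generator

`generate_panel()` emulates the input the pipeline is built for: a panel of
inbred accessions over a 3–10 kb locus, each carrying exactly one planted
haplotype profile of SNPs and 5–30 bp indels, with a canonical ATG and stop
codon and a truth table for every stage. Indel-involving variants must be
at least 20 bp apart (SNPs may be dense — published haplotypes place SNPs
13 bp apart); local context around planted indels is adjusted so each is
already left-aligned, making truth coordinates directly comparable with
calls. Everything is deterministic under the spec's seed.

What the generator does *not* emulate bounds what green tests mean:
sequencing or assembly errors, alignment artifacts at repeat boundaries,
heterozygosity, segmental duplications, and variants larger than the
alignment bound are all absent. Recovery tests therefore certify the
pipeline's logic (alignment-to-call-to-partition round trips, design/assay
consistency), not its robustness to noisy assemblies.

Templates for the transcribed markers are synthesized from each marker's
own specification (primer sites at the implied spacing, the diagnostic
site or indel planted between them, no stray recognition sites). This
closes a consistency loop over the assay engine; it validates the engine
against the marker table, not against any real genome, and the templates
are labelled synthetic accordingly.

## Problem sizes and reproducibility

The test suite exercises: exhaustive alignment-oracle agreement on 260
random pairs of length ≤ 10 (the enumeration oracle is recursion over
pending-gap states, independent of the aligner); exact recovery of planted
variants and haplotype partitions on 100 seeded panels of 4 accessions over
roughly 3–4 kb loci, plus larger spot checks; cascade designs validated on
their own panels across stages; and the full 18-marker consistency loop.
The acceptance script (`scripts/acceptance.R`) re-derives the headline
quantities from scratch at a caller-supplied seed; these sizes are the
package's chosen balance between coverage and a test run that completes in
a few minutes on one core.

## Known limitations

- No genome-wide primer specificity (e-PCR) checks; locus-internal
  uniqueness only.
- Global alignment is bounded at ~20 kb; larger structural variation must
  enter via variant tables.
- The binding and gel models are threshold simplifications; heteroduplex
  artifacts, primer-dimers and amplification efficiency are not modeled.
- No heterozygote support by design: the intended material is inbred lines.
- Multiplex panel optimization and fluorescence chemistry are out of scope.
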