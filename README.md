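# haplomark

Haplotype classification and intragenic marker design for gene-based
selection in crop panels.

Breeding programs that want to move a cloned gene's favorable allele into
elite material need two things: a haplotype classification of the gene
across their germplasm, and a cheap PCR assay that separates the favorable
haplotype from everything else. haplomark implements that workflow for
panels of inbred accessions (the motivating use case is the nitrogen-use
efficiency genes of rice, where elite haplotypes are concentrated in the
*xian*/indica subspecies and largely absent from *geng*/japonica
cultivars): it extracts a fixed analysis region around each gene, calls
variants against a reference accession, groups accessions into named
haplotypes, designs a genotyping assay for the elite haplotype through a
prioritized cascade, verifies the assay in silico, and scores panels by
elite-haplotype content.

## The method in brief

For each gene, the analysis region is the 2-kb flank upstream of the start
codon, the genic region (ATG through stop, introns included), and a 1-kb
downstream flank, with positions reported ATG-relative (+1 = the A of ATG,
−1 the base 5' of it; no zero). Accession loci are aligned globally to the
reference (affine gaps: match +2, mismatch −3, open −5, extend −2);
left-aligned SNP/indel calls define haplotypes: the reference accession is
HapA, the designated elite profile HapB, the rest HapC, HapD, ... by
frequency. Accessions with unextractable sequence or more than 5 novel
private variants are n.d.

Variants private to the target haplotype(s) are turned into an assay in a
fixed order of preference:

| Stage | Assay | Rule | Read-out |
|---|---|---|---|
| 1 | Indel | indel of 5-30 bp, amplicon 100-300 bp | band size, 4% PAGE |
| 2 | CAPS  | SNP with a differential restriction site, amplicon 100-500 bp | digestion fragments, 2% agarose |
| 3 | dCAPS | one engineered primer mismatch (positions 2-6 from the 3' end) completes a site for one allele, amplicon 100-300 bp | digestion fragments, PAGE |
| 4 | PARMS | two universal-tailed allele-specific forward primers + one common reverse | FAM/HEX fluorophore |

Oversized structural variants can still be emitted as size markers via an
explicit override. Designed assays are checked by in-silico PCR (exact
3'-terminal match, ≤ 1 mismatch in the 3' anchor) and complete digestion;
a marker passes validation only if every non-n.d. accession of a truth
panel is called concordantly and the two class patterns are separated by
the gel's resolution.

The package ships, as plain-text fixtures, a transcription of a published
survey (36 sequenced rice accessions × 14 NUE genes, with the printed
elite-count column kept alongside the recomputed one) and the matching set
of 18 published markers (12 Indel, 3 CAPS, 1 dCAPS, 2 PARMS), plus a
restriction-enzyme catalog of ~45 common commercial enzymes.

## Worked example

Simulate a 5-accession panel carrying an elite haplotype (a 20-bp promoter
insertion plus an exonic SNP), recover the haplotypes, design a marker and
validate it:

```r
library(haplomark)

spec <- panel_spec(
  seed = 42, upstream = 2000, downstream = 1000,
  exon_lengths = c(500, 450), intron_lengths = 300,
  profiles = list(
    HapA = list(),
    HapB = list(list(position = -1197, vtype = "INS", len = 20),
                list(position = 125,  vtype = "SNP"))
  ),
  assignment = c(NIP = "HapA", IR64 = "HapB", R527 = "HapB",
                 KOSH = "HapA", D62 = "HapB")
)
pn <- generate_panel(spec)
vm <- build_variant_matrix(pn$panel, pn$ref_locus, pn$model)
hs <- group_haplotypes(vm, elite_profile = pn$truth_haps$haplotypes$HapB$profile)
hs
#> <haplotype_set>
#>   HapA: 2 member(s), 0 variant(s)
#>   HapB*: 3 member(s), 2 variant(s)

cand <- select_target_variants(hs, vm, "HapB")
mk <- design_cascade(cand, pn$ref_locus, design_config(), read_enzyme_catalog(),
                     gene_label = "DEMO", model = pn$model, targets = "HapB",
                     avoid_variants = vm$variants)
mk
#> <marker_assay> DEMO 5U ID  [Indel]  targets HapB
#>   F  CCCGAAGGCTTTTATAGACCGCG
#>   R  GCTCAACATGAATACTGGTGCTCC
#>   read-out: 100 (+20)

validate_marker(mk, pn$panel, hs)$report
#>   accession haplotype fragments      call  expected concordant
#> 1       NIP      HapA       100 ref_class ref_class       TRUE
#> 2      IR64      HapB       120 alt_class alt_class       TRUE
#> 3      R527      HapB       120 alt_class alt_class       TRUE
#> 4      KOSH      HapA       100 ref_class ref_class       TRUE
#> 5       D62      HapB       120 alt_class alt_class       TRUE
```

The cascade found an in-range indel, so it emitted an Indel marker named
`DEMO 5U ID` (gene label + region of the target variant + `ID` for indel):
the reference class amplifies a 100-bp product and the elite class 120 bp
(`100 (+20)`), a difference any 4% polyacrylamide gel resolves. Every panel
accession is called concordantly with the planted truth.

Scoring the bundled 36-accession survey:

```r
sc <- score_panel(read_haplotype_survey(), elite_map())
head(sc[order(-sc$elite_count), c("accession", "group", "elite_count")], 3)
#>     accession group elite_count
#>        IR64     XI          10
#>        R527     XI          10
#>         YX1     XI          10
```

A thin command-line dispatcher over the same functions is installed at
`exec/haplomark` inside the package (subcommands `extract`, `haplotype`,
`design`, `assay`, `score`, `simulate`).

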