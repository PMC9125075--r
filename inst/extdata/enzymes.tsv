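# Default restriction-enzyme catalog: common commercial enzymes, recognition
# sites per standard commercial catalogs (REBASE nomenclature).  cut_offset is
# the top-strand cut position in bases from the 5' end of the recognition.
# Catalog order doubles as design preference order (frequent, inexpensive
# cutters first).  Type IIS enzymes cutting outside their recognition are not
# representable and are omitted.
name	recognition	cut_offset
TaqI	TCGA	1
DdeI	CTNAG	1
AluI	AGCT	2
HaeIII	GGCC	2
RsaI	GTAC	2
MseI	TTAA	1
HinfI	GANTC	1
Sau3AI	GATC	0
MspI	CCGG	1
HhaI	GCGC	3
Tsp509I	AATT	0
NlaIII	CATG	4
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
BglII	AGATCT	1
XbaI	TCTAGA	1
SalI	GTCGAC	1
PstI	CTGCAG	5
SmaI	CCCGGG	3
KpnI	GGTACC	5
SacI	GAGCTC	5
SphI	GCATGC	5
NcoI	CCATGG	1
NdeI	CATATG	2
NheI	GCTAGC	1
SpeI	ACTAGT	1
XhoI	CTCGAG	1
ApaI	GGGCCC	5
DraI	TTTAAA	3
SspI	AATATT	3
EcoRV	GATATC	3
ScaI	AGTACT	3
StuI	AGGCCT	3
HincII	GTYRAC	3
AvaI	CYCGRG	1
AvaII	GGWCC	1
BanI	GGYRCC	1
BstEII	GGTNACC	1
AflII	CTTAAG	1
AgeI	ACCGGT	1
MluI	ACGCGT	1
NsiI	ATGCAT	5
PvuI	CGATCG	4
PvuII	CAGCTG	3
SnaBI	TACGTA	3
BglI	GCCNNNNNGGC	7
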