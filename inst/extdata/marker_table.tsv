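# Transcribed published marker set: 18 intragenic assays for 14 rice NUE
# genes (12 Indel, 3 CAPS, 1 dCAPS, 2 PARMS).  Positions are ATG-relative.
# reference_size encodes the expected read-out: for Indel markers
# "<NIP amplicon> (<elite size change>)"; for CAPS/dCAPS "<NIP>/<elite>"
# where a bracketed list is a digested fragment pattern.  The printed
# enzyme name "BgI I" is interpreted as BglI (GCCNNNN^NGGC).  Lowercase
# bases mark engineered dCAPS mismatches.
gene	variation_position	marker_type	marker_name	primer_role	primer_seq	reference_size	enzyme	target_haplotypes
OsNPF6.1	-1197	Indel	NPF6.1 5U ID	F	TAATGTCCTTTCCCGTGTT	220 (+20)		HapB
				R	GTACTACTTCGGCTGTCC			
DNR1	+2165	Indel	DNR1 I4 ID	F	CGTCAATTATGGTTACCTCTG	171 (-10)		HapB
				R	GCATCTCATAGAACTGAAGAAG			
MYB61	+2346	Indel	MYB61 3U ID	F	ACTTGAATACAGGCATGGAA	205 (+26)		HapB
				R	CGTTATGCTTGTTGCTTGA			
SBM1	-325	Indel	SBM1 5U ID	F	TCGGGTGTACTACGGATC	90 (-8)		HapB
				R	GCACATACATATCAGGGA			
SBM1	+865	CAPS	SBM1 E3 S	F	TCTTCAACTGGATCAACTTC	380/(100,280)	BglI	HapB, HapD
				R	TACATCACGGTGGTCATC			
NGR2	-935	CAPS	NGR2 5U S	F	TCATTGACCTACGGTTGC	(249,24)/273	TaqI	HapB
				R	GCTGCTCCAACATCTTCT			
NGR2	+1701	PARMS	NGR2 I3 S	FC	GAAGGTGACCAAGTTCATGCTAGTAGTACTACTTCGATTTGGTGCT			HapB
				FT	GAAGGTCGGAGTCAACGGATTAGTAGTACTACTTCGATTTGGTGCC			
				R	GCAGTGCAGAGAGTAAAGTTTCAG			
OsNR2	+2202	Indel	NR2 E4 ID	F	TCACGTCCATCGTTGAGA	120 (+12)		HapB
				R	ACAGGCTCTTCTTGTCCAT			
NGR5	-1565	Indel	NGR5 5U ID	F	AGAACACACGGGATAGGAT	210 (-13)		HapB, HapC, HapD
				R	GAATCACTTGCTCGCTAGA			
NGR5	+3326	PARMS	NGR5 I6 S	FC	GAAGGTGACCAAGTTCATGCTATCTCGCTGTCCTAAACGACTTCC			HapB
				FT	GAAGGTCGGAGTCAACGGATTATCTCGCTGTCCTAAACGACTTCT			
				R	GAATTACGTACACCCTCCGTACTC			
OsTCP19	-2022	Indel	TCP19 5U ID	F	AACTCTTCAGGGTTCTTGC	231 (-29)		HapB
				R	GTGCCGTGTCACATAGAG			
ARE1	-393	Indel	ARE1 5U ID	F	CCGTGTCTTATCCACTCC	115 (+6)		HapB
				R	ATGGGGATCGATACGATG			
ARE1	-723	CAPS	ARE1 5U S	F	TTAACACTTGTGGCAATGAC	320/(100,210)	DdeI	HapC
				R	CTAGTACCGTATTGGCTGTT			
DEP1	+3454	Indel	DEP1 E5 ID	F	GACCAAGGTGCCTCAATT	1085 (-615)		HapB
				R	TTCAACCTCGTCTCATAGC			
NAC42	+3508	dCAPS	NAC42 3U S	F	TACGTGACTTCGACGGCtGA	(100,20)/120	DdeI	HapB
				R	ACGGTCCAAATGCTGCTTCG			
NLP4	-1771	Indel	NLP4 5U ID	F	AAGTCCTTCCTAAACTGAGA	136 (-6)		HapB
				R	GGTCTGTTCCAAACAAAGAT			
NRT1.1B	+2825	Indel	NRT1.1B I1 ID	F	CATATTTGTTGGCTGCTAAC	178 (+16)		HapB
				R	GGTGGTTCTAACGGTCAA			
TOND1	-1205	Indel	TOND1 5U ID	F	TTTGGGTCCCTGACAATA	153 (+8)		HapB
				R	TGGAACAACTCAAGTAGCA			
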