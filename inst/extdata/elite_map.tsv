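# Default elite-haplotype map for the 14 NUE genes: the haplotype(s) of each
# gene associated with improved nitrogen-use efficiency in the source survey
# (HapB throughout; ARE1 additionally HapC, whose large 5' insertion likely
# lowers expression).  SBM1 HapD is deliberately excluded by default (its
# elite status is unresolved); include it via elite_map(include_sbm1_hapd=TRUE).
gene	elite_haplotypes
OsNPF6.1	HapB
DNR1	HapB
MYB61	HapB
SBM1	HapB
NGR2	HapB
OsNR2	HapB
NGR5	HapB
OsTCP19	HapB
ARE1	HapB, HapC
DEP1	HapB
NAC42	HapB
OsNLP4	HapB
NRT1.1B	HapB
TOND1	HapB
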