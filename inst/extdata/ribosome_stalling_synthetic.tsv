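# SYNTHETIC stand-in per-codon ribosome A-site pause values
# (arbitrary units). Generated, not measured: uniform random in [0.5, 2.5].
# Supply a measured pausing table for real analyses via stall_table().
codon	pause
TTT	2.29
TTC	1.63
TTA	1.41
TTG	1.3
CTT	0.67
CTC	1.76
CTA	1.43
CTG	1.64
ATT	1.82
ATC	2.26
ATA	1.26
ATG	1.95
GTT	2.22
GTC	0.87
GTA	1.77
GTG	1.94
TCT	1.58
TCC	0.91
TCA	2.3
TCG	0.75
CCT	2.4
CCC	2.06
CCA	2.42
CCG	0.73
ACT	2.46
ACC	1.74
ACA	2.35
ACG	0.9
GCT	0.93
GCC	2.34
GCA	1.94
GCG	2.02
TAT	1.07
TAC	1.19
TAA	1.18
TAG	2.08
CAT	1.23
CAC	1.83
CAA	1.25
CAG	0.74
AAT	2.16
AAC	1.34
AAA	0.66
AAG	0.85
GAT	0.86
GAC	1.85
GAA	1.71
GAG	1.02
TGT	1.68
TGC	1.32
TGA	2.23
TGG	0.72
CGT	1.14
CGC	0.84
CGA	0.6
CGG	1.61
AGT	0.78
AGC	0.82
AGA	2.06
AGG	1.39
GGT	0.76
GGC	1.63
GGA	2.05
GGG	1.34
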