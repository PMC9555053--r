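# SYNTHETIC stand-in tRNA abundance table (arbitrary units).
# Generated, not measured: values loosely track codon usage with random
# jitter. Supply a measured table (e.g. Dong et al. 1996 assignments) for
# real analyses via trna_table().
codon	abundance
TTT	26.7
TTC	18.4
TTA	10.9
TTG	12.4
CTT	12.5
CTC	7.8
CTA	4.8
CTG	68.8
ATT	25.3
ATC	27.7
ATA	3.5
ATG	33.2
GTT	15.4
GTC	20.6
GTA	8.9
GTG	24.4
TCT	9.7
TCC	6.2
TCA	7.2
TCG	6.5
CCT	7.1
CCC	5.8
CCA	7.6
CCG	16.1
ACT	9.4
ACC	18.5
ACA	7.6
ACG	11.3
GCT	10.2
GCC	28.6
GCA	27.7
GCG	25.9
TAT	20.2
TAC	8.5
CAT	14.8
CAC	10.1
CAA	12.8
CAG	29.3
AAT	22.3
AAC	21.8
AAA	31.1
AAG	14.4
GAT	31.4
GAC	19.2
GAA	27.2
GAG	12.2
TGT	8
TGC	6.3
TGG	16.4
CGT	17.5
CGC	31.3
CGA	5
CGG	8.4
AGT	12.5
AGC	17.4
AGA	3.5
AGG	2.4
GGT	16.7
GGC	41.4
GGA	7.1
GGG	10.3
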