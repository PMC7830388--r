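trinucleotide	value
AAA	-0.05
AAC	-0.23
AAG	0.002
AAT	-0.06
ACA	-0.01
ACC	-0.126
ACG	-0.008
ACT	-0.195
AGA	-0.233
AGC	0.074
AGG	0.139
ATA	-0.079
ATC	-0.244
ATG	0.084
CAA	-0.052
CAC	0.072
CAG	-0.123
CCA	0.159
CCC	-0.135
CCG	0.145
CGA	0.074
CGC	-0.071
CTA	-0.224
CTC	-0.208
GAA	0.085
GAC	-0.072
GCA	0.059
GCC	-0.143
GGA	-0.028
GTA	0.054
TAA	-0.062
TCA	0.044
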