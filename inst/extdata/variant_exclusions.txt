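# Terms tagged as variants that are not variants (cell lines etc.);
# matched case-insensitively against the full mention text.
T47D
HEK293
U937
K562
A549
MCF7
HL60
SW480
H1975
LNCaP
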