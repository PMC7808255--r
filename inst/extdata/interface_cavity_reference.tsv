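mutant	interface_cavity
Tyr	422
K142M	137
T325A	320
S323R	810
W39R	1648
R402G	3709
M370V	2041
V393D	6766
R77G	4154
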