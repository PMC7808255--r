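mutation	ddg	dd_v
W39R	1.2	1248
R77G	5.7	1670
K142M	-1.7	928
S323R	0.8	255
T325A	-0.3	540
M370V	4.5	579
V393D	4.8	1656
R402G	2.1	685
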