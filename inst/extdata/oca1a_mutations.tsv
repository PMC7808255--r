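mutation	ddg	dd_v	dd_sa
H180N	-0.95	563	705
H180R	2.16	1178	1020
H202R	2.81	66	49
H202Q	1.36	-294	54
H211R	9.24	-435	-376
H363T	-1.46	1255	1419
H363R	-0.80	1505	1610
H363Y	1.58	-632	-314
H367Y	0.93	-285	-36
H367R	-0.91	813	927
H390D	-0.17	-178	146
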