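model	cu_distance_0ns	cu_distance_4ns	cu_distance_25ns
WT	5.7	8.2	8.2
H180N	6.1	14.8	13.4
H180R	6.3	8.7	19.2
H202R	8.0	7.7	5.7
H202Q	6.4	11.6	12.4
H211R	7.4	6.8	11.9
H363T	7.4	51.4	44.9
H363R	6.1	43.3	50.8
H363Y	4.9	5.9	5.9
H367Y	5.4	4.6	4.3
H367R	5.7	6.2	29.6
H390D	5.4	5.4	14.0
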