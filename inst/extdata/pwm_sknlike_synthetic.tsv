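A	5	8	2	0	1	0	28	1	0	25
C	2	1	2	0	0	30	1	0	28	2
G	3	1	1	30	0	0	1	0	1	1
T	20	20	25	0	29	0	0	29	1	2
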