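position	weight	label
1	3.0	CM-custom
2	0.5	CM-custom
3	2.0	CM-custom
4	4.0	CM-custom
5	2.0	CM-custom
6	0.5	CM-custom
7	1.0	CM-custom
8	1.0	CM-custom
9	2.0	CM-custom
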