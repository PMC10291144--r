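position	weight	label
1	3.0	CM-crystal
2	0.5	CM-crystal
3	0.5	CM-crystal
4	4.0	CM-crystal
5	2.0	CM-crystal
6	0.5	CM-crystal
7	1.0	CM-crystal
8	1.0	CM-crystal
9	0.5	CM-crystal
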