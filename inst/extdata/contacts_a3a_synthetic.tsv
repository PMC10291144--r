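# synthetic GetContacts-style fixture emulating the static A3A TCR-peptide
# contact pattern (peptide chain C, TCR chains D/E); per-position totals
# 3,0,0,4,2,0,1,1,0
0	hbbb	D:SER:31:OG	C:GLU:1:N
0	sb	D:ARG:28:NH1	C:GLU:1:OE1
0	vdw	E:TYR:100:CZ	C:GLU:1:CB
0	vdw	D:GLY:97:CA	C:PRO:4:CG
0	hp	D:ALA:98:CB	C:PRO:4:CB
0	hbsb	E:ASN:92:ND2	C:PRO:4:O
0	vdw	E:LEU:95:CD1	C:PRO:4:CA
0	hbss	D:TYR:32:OH	C:ILE:5:O
0	hp	D:TYR:32:CE1	C:ILE:5:CD1
0	vdw	E:PHE:30:CZ	C:HIS:7:CE1
0	hp	D:MET:55:CE	C:LEU:8:CD2
0	hbbb	A:LYS:66:NZ	D:ASP:56:OD1
0	vdw	A:ARG:65:CZ	E:TYR:48:CE1
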