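residue	atom	charge
STR	C	0.6
STR	O	-0.6
STR	N	-0.4
STR	H	0.4
STR	NZ	-0.3
STR	HZ1	0.4333333333333333
STR	HZ2	0.4333333333333333
STR	HZ3	0.4333333333333333
CL	CL	-1.0
NA	NA	1.0
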