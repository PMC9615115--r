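residue	atom	charge
TIP4	O	0.0
TIP4	H1	0.52422
TIP4	H2	0.52422
TIP4	M	-1.04844
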