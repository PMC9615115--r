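residue	atom	charge
HOH	O	-0.834
HOH	H1	0.417
HOH	H2	0.417
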