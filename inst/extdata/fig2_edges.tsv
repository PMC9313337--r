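source	target	interaction	provenance	source_compartment	target_compartment
A	C	activation	original	membrane	cytoplasm
A	B	activation	original	membrane	cytoplasm
D	A	inhibition	original	cytoplasm	membrane
B	D	activation	original	cytoplasm	cytoplasm
C	D	activation	original	cytoplasm	cytoplasm
E	D	inhibition	original	nucleus	cytoplasm
D	E	activation	original	cytoplasm	nucleus
E	F	activation	original	nucleus	unknown
E	G	expression	original	nucleus	unknown
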