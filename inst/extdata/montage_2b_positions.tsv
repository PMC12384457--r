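label	x	y
C3	-0.4	0
Cz	0	0
C4	0.4	0
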