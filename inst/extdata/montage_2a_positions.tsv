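label	x	y
Fz	0	0.4
FC3	-0.409232	0.215146
FC1	-0.203597	0.203597
FCz	0	0.2
FC2	0.203597	0.203597
FC4	0.409232	0.215146
C5	-0.6	0
C3	-0.4	0
C1	-0.2	0
Cz	0	0
C2	0.2	0
C4	0.4	0
C6	0.6	0
CP3	-0.409232	-0.215146
CP1	-0.203597	-0.203597
CPz	0	-0.2
CP2	0.203597	-0.203597
CP4	0.409232	-0.215146
P1	-0.215146	-0.409232
Pz	0	-0.4
P2	0.215146	-0.409232
POz	0	-0.6
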