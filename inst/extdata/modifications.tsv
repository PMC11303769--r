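name	composition	residues	nterm	mass
Oxidation	O1	FHKMPWY	FALSE	15.994915
Deamidation	H-1 N-1 O1	NQR	FALSE	0.984016
Dioxidation	O2	FMPWY	FALSE	31.989829
Phosphorylation	H1 O3 P1	S	FALSE	79.966330
Acetyl	C2 H2 O1		TRUE	42.010565
Gln->pyro-Glu	H-3 N-1	Q	TRUE	-17.026549
Glu->pyro-Glu	H-2 O-1	E	TRUE	-18.010565
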