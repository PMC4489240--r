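# Characteristic backbone torsion angles (degrees) of the central two
# residues (i+1, i+2) for the five common beta-turn types.
type	phi1	psi1	phi2	psi2
I	-60	-30	-90	0
II	-60	120	80	0
I'	60	30	90	0
II'	60	-120	-80	0
VIII	-60	-30	-120	120
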