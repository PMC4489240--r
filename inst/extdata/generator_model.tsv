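# Emission model for the synthetic-protein generator.
#
# Mean secondary shifts (ppm) per structural state and nucleus. Structured
# states emit at ~2x the CSI filter cutoffs so that, at zero noise, the
# ternary filter inverts them exactly; edge strands emit at 1.5x the cutoffs
# (edge_scale below, applied to the strand means) which lowers their apparent
# rigidity; ordered coil emits sub-threshold but appreciable magnitudes
# (|delta| = 0.7x cutoff, alternating sign) so turn regions stay above the
# S2 > 0.7 gate; disordered segments emit near-zero magnitudes.
#
key	value
helix_HA	-0.20
helix_CA	1.40
helix_CB	-1.40
helix_C	1.00
strand_HA	0.20
strand_CA	-1.40
strand_CB	1.40
strand_C	-1.00
edge_scale	0.75
coil_HA	0.07
coil_CA	0.49
coil_CB	0.49
coil_C	0.35
disordered_HA	0.005
disordered_CA	0.035
disordered_CB	0.035
disordered_C	0.025
# Gaussian noise sd per nucleus (ppm) at the default noise level; scaled by
# the noise_scale argument of generator_model().
noise_sd_HA	0.02
noise_sd_CA	0.10
noise_sd_CB	0.10
noise_sd_C	0.10
noise_sd_N	0.10
noise_sd_H	0.02
# Backbone torsion emission (degrees); turn centrals use the canonical table.
helix_phi	-63
helix_psi	-42
strand_phi	-120
strand_psi	135
coil_phi	-120
coil_psi	140
angle_noise_sd	5
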