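# Per-nucleus CSI digital-filter cutoffs (ppm). A secondary shift must
# strictly exceed the cutoff in magnitude to count as "significant".
atom	threshold
HA	0.1
CA	0.7
CB	0.7
C	0.5
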