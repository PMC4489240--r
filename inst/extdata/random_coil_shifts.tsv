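# Residue-specific random-coil chemical shifts (ppm), classic CSI-era
# reference values for backbone nuclei. Glycine has no CB; proline has no
# amide H. Override with a file of the same layout via random_coil_table(path).
aa	H	HA	CA	CB	C	N
A	8.24	4.32	52.5	19.0	177.8	123.8
R	8.23	4.34	56.0	30.9	176.3	120.5
N	8.40	4.74	52.8	37.9	175.2	118.7
D	8.34	4.64	54.2	41.1	176.3	120.4
C	8.32	4.71	56.9	28.9	174.1	118.8
Q	8.32	4.34	56.6	29.4	176.0	119.8
E	8.42	4.35	56.6	29.9	176.6	120.2
G	8.33	3.96	45.1	NA	174.9	108.8
H	8.42	4.73	55.0	29.0	174.1	118.2
I	8.00	4.17	61.1	38.8	176.4	119.9
L	8.16	4.32	55.1	42.4	177.6	121.8
K	8.29	4.32	56.2	33.1	176.6	120.4
M	8.28	4.48	55.4	32.9	176.3	119.6
F	8.30	4.62	57.7	39.6	175.8	120.3
P	NA	4.42	63.3	32.1	177.3	128.1
S	8.31	4.47	58.3	63.8	174.6	115.7
T	8.15	4.35	61.8	69.8	174.7	113.6
W	8.25	4.66	57.5	29.6	176.1	121.3
Y	8.12	4.55	57.9	38.8	175.9	120.3
V	8.19	4.12	62.2	32.9	176.3	119.2
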