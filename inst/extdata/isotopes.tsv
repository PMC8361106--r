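symbol	monoisotopic_mass	nominal_mass	isotope_shift	abundance
H	1.00782503207	1	0	0.999885
H	1.00782503207	1	1	0.000115
C	12.0	12	0	0.9893
C	12.0	12	1	0.0107
N	14.0030740048	14	0	0.99636
N	14.0030740048	14	1	0.00364
O	15.9949146196	16	0	0.99757
O	15.9949146196	16	1	0.00038
O	15.9949146196	16	2	0.00205
Si	27.9769265325	28	0	0.92223
Si	27.9769265325	28	1	0.04685
Si	27.9769265325	28	2	0.03092
S	31.9720710015	32	0	0.9499
S	31.9720710015	32	1	0.0075
S	31.9720710015	32	2	0.0425
S	31.9720710015	32	4	0.0001
P	30.9737616320	31	0	1
F	18.9984031630	19	0	1
Na	22.9897692809	23	0	1
K	38.9637064864	39	0	0.932581
K	38.9637064864	39	1	0.000117
K	38.9637064864	39	2	0.067302
Cl	34.9688526800	35	0	0.7576
Cl	34.9688526800	35	2	0.2424
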