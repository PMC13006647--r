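strain_id	kind	position	payload	label
minusOSC	insertion	6	GA	+2 GA
minusOSC	deletion	5	1	-1C
minusOSC	deletion	11	1	-1A (x2)
minusOSC	insertion	9	CC	+2 CC
minusOSC	deletion	17	1	-1A (x5)
minusOSC	deletion	20	1	-1A
minusOSC	deletion	22	1	-1T (x1)
minusOSC	insertion	18	GG	+2 GG
minusOSC	insertion	21	CA	+2 CA
minusOSC	insertion	15	CT	+2 CT
minusOSC	insertion	19	AT	+2 AT
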