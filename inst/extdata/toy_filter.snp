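rs1	1	0	100	A	C
rs2	1	0	200	A	C
rs3	1	0	300	A	C
rs4	1	0	340	A	C
rs5	1	0	400	A	C
rs6	1	0	500	A	C
rs7	1	0	600	A	C
rs8	1	0	700	A	C
rs9	1	0	800	A	C
rs10	1	0	900	A	C
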