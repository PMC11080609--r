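sample_id	size_bp	height	area	scan
P01_blood	145	180	5120	2101
P01_blood	148	510	2650	2140
P01_blood	151	1010	5300	2180
P01_blood	286	420	2140	3842
P01_blood	289	910	4710	3880
P01_blood	292	2030	10560	3921
P01_blood	295	640	3320	3960
P01_blood	298	250	1290	4001
P01_blood	301	105	540	4040
P01_blood	304	64	330	4081
P02_blood	145	210	5700	2099
P02_blood	148	560	2880	2138
P02_blood	151	1150	5980	2179
P02_blood	277	380	1980	3720
P02_blood	280	820	4220	3761
P02_blood	283	1870	9660	3800
P02_blood	286	410	2120	3841
P02_blood	289	150	760	3880
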