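group	subject	tissue	gestational_week	age	modal_cag	ei
SCA1	fetus	frontal_cortex	18	NA	59	0.053
SCA1	fetus	temporal_cortex	18	NA	59	0.057
SCA1	fetus	cerebellum	18	NA	59	0.058
SCA1	fetus	spinal_cord	18	NA	59	0.090
SCA3	fetus	cortex	13	NA	NA	0.066
SCA7	fetus	cortex	14	NA	47	0.037
SCA3	trophoblast	trophoblast	12	NA	NA	0.041
SCA7	trophoblast	trophoblast	11	NA	NA	0.102
SCA1	parent	blood	NA	26	58	1.329
SCA3	parent	blood	NA	25	73	0.401
SCA7	parent	blood	NA	30	45	1.803
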