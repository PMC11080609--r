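individual	group	sex	age_death	diagnostic_cag	tissue	modal_cag	ei	age_at_sample
1	SCA1	M	42	55	cerebellum	54	1.26	NA
1	SCA1	M	42	55	thalamus	NA	3.42	NA
1	SCA1	M	42	55	pallidum	NA	3.22	NA
1	SCA1	M	42	55	caudate	NA	3.04	NA
1	SCA1	M	42	55	amygdala	NA	2.45	NA
1	SCA1	M	42	55	frontal_cortex	NA	3.52	NA
2	SCA1	F	57	49	cerebellum	NA	0.31	NA
3	SCA1	M	50	49	cerebellum	NA	0.36	NA
4	SCA2	M	35	47	cerebellum	NA	0.37	NA
4	SCA2	M	35	47	dentate	NA	0.49	NA
4	SCA2	M	35	47	pons	NA	1.46	NA
4	SCA2	M	35	47	medulla_oblongata	NA	1.28	NA
4	SCA2	M	35	47	midbrain	NA	0.39	NA
4	SCA2	M	35	47	thalamus	NA	1.30	NA
4	SCA2	M	35	47	pallidum	NA	1.31	NA
4	SCA2	M	35	47	amygdala	NA	1.80	NA
4	SCA2	M	35	47	primary_motor_cortex	NA	1.69	NA
4	SCA2	M	35	47	frontal_cortex	NA	2.18	NA
4	SCA2	M	35	47	blood	NA	0.79	18
4	SCA2	M	35	47	blood	NA	0.94	17
4	SCA2	M	35	47	blood	NA	1.20	33
4	SCA2	M	35	47	blood	NA	1.20	34
5	SCA3	F	68	73	cerebellum	72	0.76	NA
5	SCA3	F	68	73	thalamus	NA	1.70	NA
5	SCA3	F	68	73	pallidum	NA	1.43	NA
5	SCA3	F	68	73	primary_motor_cortex	NA	1.79	NA
5	SCA3	F	68	73	frontal_cortex	NA	2.01	NA
5	SCA3	F	68	73	blood	NA	0.91	56
5	SCA3	F	68	73	blood	NA	0.92	65
6	SCA3	M	42	78	cerebellum	77	0.77	NA
6	SCA3	M	42	78	pons_body	NA	1.67	NA
6	SCA3	M	42	78	pons_head	NA	1.66	NA
6	SCA3	M	42	78	olive	NA	1.59	NA
6	SCA3	M	42	78	medulla_oblongata	NA	1.25	NA
6	SCA3	M	42	78	midbrain_tegmentum	NA	1.25	NA
6	SCA3	M	42	78	substantia_nigra	NA	1.57	NA
6	SCA3	M	42	78	thalamus	NA	1.67	NA
6	SCA3	M	42	78	pallidum	NA	1.33	NA
6	SCA3	M	42	78	primary_motor_cortex	NA	1.73	NA
6	SCA3	M	42	78	frontal_cortex	NA	1.74	NA
7	SCA3	F	56	74	cerebellum	73	0.59	NA
7	SCA3	F	56	74	pons_body	NA	1.64	NA
7	SCA3	F	56	74	pons_head	NA	1.65	NA
7	SCA3	F	56	74	olive	NA	1.31	NA
7	SCA3	F	56	74	medulla_oblongata	NA	1.18	NA
7	SCA3	F	56	74	midbrain_tegmentum	NA	1.37	NA
7	SCA3	F	56	74	substantia_nigra	NA	1.39	NA
7	SCA3	F	56	74	primary_motor_cortex	NA	1.39	NA
7	SCA3	F	56	74	frontal_cortex	NA	1.60	NA
7	SCA3	F	56	74	blood	NA	0.61	39
7	SCA3	F	56	74	blood	NA	0.65	45
8	SCA3	F	72	70	cerebellum	69	0.42	NA
8	SCA3	F	72	70	pons_body	NA	1.83	NA
8	SCA3	F	72	70	pons_head	NA	1.87	NA
8	SCA3	F	72	70	olive	NA	1.75	NA
8	SCA3	F	72	70	midbrain_tegmentum	NA	1.70	NA
8	SCA3	F	72	70	substantia_nigra	NA	1.65	NA
8	SCA3	F	72	70	primary_motor_cortex	NA	1.75	NA
8	SCA3	F	72	70	frontal_cortex	NA	1.81	NA
9	SCA7	M	55	42	cerebellum	NA	0.52	NA
9	SCA7	M	55	42	pons	NA	1.56	NA
9	SCA7	M	55	42	olive	NA	1.72	NA
9	SCA7	M	55	42	primary_motor_cortex	NA	1.38	NA
9	SCA7	M	55	42	primary_visual_cortex	NA	1.72	NA
9	SCA7	M	55	42	frontal_cortex	NA	1.55	NA
10	SCA7	M	56	42	cerebellum	NA	0.56	NA
10	SCA7	M	56	42	pons_body	NA	2.28	NA
10	SCA7	M	56	42	pons_head	NA	2.01	NA
10	SCA7	M	56	42	olive	NA	1.86	NA
10	SCA7	M	56	42	midbrain_tegmentum	NA	1.81	NA
10	SCA7	M	56	42	substantia_nigra	NA	2.23	NA
10	SCA7	M	56	42	thalamus	NA	1.76	NA
10	SCA7	M	56	42	primary_motor_cortex	NA	1.60	NA
10	SCA7	M	56	42	primary_visual_cortex	NA	2.71	NA
10	SCA7	M	56	42	frontal_cortex	NA	1.86	NA
10	SCA7	M	56	42	blood	NA	1.89	31
10	SCA7	M	56	42	blood	NA	2.85	44
10	SCA7	M	56	42	blood	NA	3.81	51
11	SCA1	M	42	54	blood	NA	1.10	27
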