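sample_id	individual_id	gene	tissue	age	plate_id
P01_blood	IND01	ATXN3	blood	48	plateA
P02_blood	IND02	ATXN3	blood	39	plateA
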