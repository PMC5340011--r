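"sample_id","waist_cm","glucose_mgdl","hdl_mgdl","sbp_mmhg","dbp_mmhg","tg_mgdl","med_diabetes","med_cholesterol","med_htn","med_tg"
"subj1",95,92,52,118,76,110,FALSE,FALSE,FALSE,FALSE
"subj2",104,105,38,135,88,160,FALSE,FALSE,TRUE,FALSE
"subj3",110,118,35,142,92,210,TRUE,FALSE,FALSE,FALSE
"subj4",88,88,60,110,70,90,FALSE,FALSE,FALSE,FALSE
"subj5",101,100,44,128,84,150,FALSE,TRUE,FALSE,FALSE
"subj6",120,130,30,150,95,260,TRUE,FALSE,TRUE,FALSE
"subj7",99,97,41,131,80,140,FALSE,FALSE,FALSE,FALSE
"subj8",103,99,39,125,86,155,FALSE,FALSE,FALSE,FALSE
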