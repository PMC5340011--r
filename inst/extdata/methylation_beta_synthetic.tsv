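sample_id	cg00000029	cg00000108	cg00000165	cg00000236	cg00000289	cg00000363
subj1	0.84	0.345	0.34	0.288	0.801	0.584
subj2	0.742	0.383	0.148	NA	0.217	0.084
subj3	0.301	0.694	0.31	0.866	0.51	0.448
subj4	0.526	0.732	0.788	0.943	0.477	0.47
subj5	NA	0.052	0.493	0.108	0.469	0.738
subj6	0.932	0.719	0.077	0.658	0.869	0.442
subj7	0.132	0.223	0.446	0.348	0.636	0.63
subj8	0.114	0.457	0.12	0.453	0.282	0.724
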