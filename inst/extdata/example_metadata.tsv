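sample_id	subject_id	visit_index
subj_001_v01	subj_001	1
subj_001_v02	subj_001	2
subj_001_v03	subj_001	3
subj_001_v04	subj_001	4
subj_002_v01	subj_002	1
subj_002_v02	subj_002	2
subj_002_v03	subj_002	3
subj_002_v04	subj_002	4
subj_003_v01	subj_003	1
subj_003_v02	subj_003	2
subj_003_v03	subj_003	3
subj_003_v04	subj_003	4
subj_004_v01	subj_004	1
subj_004_v02	subj_004	2
subj_004_v03	subj_004	3
subj_004_v04	subj_004	4
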