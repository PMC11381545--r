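species_id	subj_001_v01	subj_001_v02	subj_001_v03	subj_001_v04	subj_002_v01	subj_002_v02	subj_002_v03	subj_002_v04	subj_003_v01	subj_003_v02	subj_003_v03	subj_003_v04	subj_004_v01	subj_004_v02	subj_004_v03	subj_004_v04
sp_0001	484200	0	772200	0	0	514600	0	401400	894800	0	759800	0	969200	0	949400	791000
sp_0002	0	0	0	0	0	0	0	0	61400	0	0	0	0	0	0	0
sp_0003	208400	0	0	0	0	447400	0	0	0	942000	219400	787800	0	329600	40800	0
sp_0004	46800	3800	0	70600	81600	0	18400	106800	3000	17200	1400	0	2200	136000	0	115400
sp_0005	0	37600	123600	193800	0	0	257200	0	31200	40800	9800	145400	2000	473000	9400	0
sp_0006	64400	9400	0	44200	367600	11400	337600	106200	9600	0	9600	43200	26600	51800	400	93600
sp_0007	196200	949200	104200	538800	550800	0	386800	272200	0	0	0	0	0	0	0	0
sp_0008	0	0	0	152600	0	26600	0	113400	0	0	0	23600	0	9600	0	0
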