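config	age	total_cholesterol	hdl	sbp	bp_treated	smoker	diabetes	expected_risk_pct
pce_white_male	55	213	50	120	0	0	0	5.4
pce_white_female	55	213	50	120	0	0	0	2.1
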