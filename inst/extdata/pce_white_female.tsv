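covariate	transform	coefficient
age	log	-29.799
age:age	log:log	4.884
total_cholesterol	log	13.54
age:total_cholesterol	log:log	-3.114
hdl	log	-13.578
age:hdl	log:log	3.149
sbp_treated	log	2.019
sbp_untreated	log	1.957
smoker	identity	7.574
age:smoker	log:identity	-1.665
diabetes	identity	0.661
.baseline_survival	.	0.9665
.mean_lp	.	-29.18
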