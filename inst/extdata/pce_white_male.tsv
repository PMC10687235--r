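covariate	transform	coefficient
age	log	12.344
total_cholesterol	log	11.853
age:total_cholesterol	log:log	-2.664
hdl	log	-7.99
age:hdl	log:log	1.769
sbp_treated	log	1.797
sbp_untreated	log	1.764
smoker	identity	7.837
age:smoker	log:identity	-1.795
diabetes	identity	0.658
.baseline_survival	.	0.9144
.mean_lp	.	61.18
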