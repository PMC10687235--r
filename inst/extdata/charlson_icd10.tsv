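condition	prefix	weight
myocardial_infarction	I21	1
myocardial_infarction	I22	1
myocardial_infarction	I25.2	1
congestive_heart_failure	I09.9	1
congestive_heart_failure	I11.0	1
congestive_heart_failure	I13.0	1
congestive_heart_failure	I13.2	1
congestive_heart_failure	I25.5	1
congestive_heart_failure	I42	1
congestive_heart_failure	I43	1
congestive_heart_failure	I50	1
peripheral_vascular_disease	I70	1
peripheral_vascular_disease	I71	1
peripheral_vascular_disease	I73.1	1
peripheral_vascular_disease	I73.8	1
peripheral_vascular_disease	I73.9	1
peripheral_vascular_disease	I77.1	1
peripheral_vascular_disease	I79.0	1
peripheral_vascular_disease	K55.1	1
peripheral_vascular_disease	Z95.8	1
peripheral_vascular_disease	Z95.9	1
cerebrovascular_disease	G45	1
cerebrovascular_disease	G46	1
cerebrovascular_disease	I60	1
cerebrovascular_disease	I61	1
cerebrovascular_disease	I62	1
cerebrovascular_disease	I63	1
cerebrovascular_disease	I64	1
cerebrovascular_disease	I65	1
cerebrovascular_disease	I66	1
cerebrovascular_disease	I67	1
cerebrovascular_disease	I68	1
cerebrovascular_disease	I69	1
dementia	F00	1
dementia	F01	1
dementia	F02	1
dementia	F03	1
dementia	F05.1	1
dementia	G30	1
dementia	G31.1	1
chronic_pulmonary_disease	I27.8	1
chronic_pulmonary_disease	I27.9	1
chronic_pulmonary_disease	J40	1
chronic_pulmonary_disease	J41	1
chronic_pulmonary_disease	J42	1
chronic_pulmonary_disease	J43	1
chronic_pulmonary_disease	J44	1
chronic_pulmonary_disease	J45	1
chronic_pulmonary_disease	J46	1
chronic_pulmonary_disease	J47	1
chronic_pulmonary_disease	J60	1
chronic_pulmonary_disease	J61	1
chronic_pulmonary_disease	J62	1
chronic_pulmonary_disease	J63	1
chronic_pulmonary_disease	J64	1
chronic_pulmonary_disease	J65	1
chronic_pulmonary_disease	J66	1
chronic_pulmonary_disease	J67	1
rheumatic_disease	M05	1
rheumatic_disease	M06	1
rheumatic_disease	M31.5	1
rheumatic_disease	M32	1
rheumatic_disease	M33	1
rheumatic_disease	M34	1
rheumatic_disease	M35.1	1
rheumatic_disease	M35.3	1
rheumatic_disease	M36.0	1
peptic_ulcer_disease	K25	1
peptic_ulcer_disease	K26	1
peptic_ulcer_disease	K27	1
peptic_ulcer_disease	K28	1
mild_liver_disease	B18	1
mild_liver_disease	K70.0	1
mild_liver_disease	K70.1	1
mild_liver_disease	K70.2	1
mild_liver_disease	K70.3	1
mild_liver_disease	K70.9	1
mild_liver_disease	K73	1
mild_liver_disease	K74	1
mild_liver_disease	K76.0	1
mild_liver_disease	Z94.4	1
diabetes_uncomplicated	E10.0	1
diabetes_uncomplicated	E10.1	1
diabetes_uncomplicated	E10.6	1
diabetes_uncomplicated	E10.8	1
diabetes_uncomplicated	E10.9	1
diabetes_uncomplicated	E11.0	1
diabetes_uncomplicated	E11.1	1
diabetes_uncomplicated	E11.6	1
diabetes_uncomplicated	E11.8	1
diabetes_uncomplicated	E11.9	1
diabetes_uncomplicated	E13.0	1
diabetes_uncomplicated	E13.1	1
diabetes_uncomplicated	E13.9	1
diabetes_complicated	E10.2	2
diabetes_complicated	E10.3	2
diabetes_complicated	E10.4	2
diabetes_complicated	E10.5	2
diabetes_complicated	E10.7	2
diabetes_complicated	E11.2	2
diabetes_complicated	E11.3	2
diabetes_complicated	E11.4	2
diabetes_complicated	E11.5	2
diabetes_complicated	E11.7	2
hemiplegia_paraplegia	G04.1	2
hemiplegia_paraplegia	G11.4	2
hemiplegia_paraplegia	G80.1	2
hemiplegia_paraplegia	G80.2	2
hemiplegia_paraplegia	G81	2
hemiplegia_paraplegia	G82	2
renal_disease	I12.0	2
renal_disease	I13.1	2
renal_disease	N18	2
renal_disease	N19	2
renal_disease	N25.0	2
renal_disease	Z49	2
renal_disease	Z94.0	2
renal_disease	Z99.2	2
malignancy	C0	2
malignancy	C1	2
malignancy	C2	2
malignancy	C30	2
malignancy	C31	2
malignancy	C32	2
malignancy	C33	2
malignancy	C34	2
malignancy	C37	2
malignancy	C38	2
malignancy	C39	2
malignancy	C40	2
malignancy	C41	2
malignancy	C43	2
malignancy	C45	2
malignancy	C46	2
malignancy	C47	2
malignancy	C48	2
malignancy	C49	2
malignancy	C50	2
malignancy	C5	2
malignancy	C6	2
malignancy	C70	2
malignancy	C71	2
malignancy	C72	2
malignancy	C73	2
malignancy	C74	2
malignancy	C75	2
malignancy	C76	2
malignancy	C81	2
malignancy	C82	2
malignancy	C83	2
malignancy	C84	2
malignancy	C85	2
malignancy	C88	2
malignancy	C90	2
malignancy	C91	2
malignancy	C92	2
malignancy	C93	2
malignancy	C94	2
malignancy	C95	2
malignancy	C96	2
malignancy	C97	2
severe_liver_disease	I85.0	3
severe_liver_disease	I85.9	3
severe_liver_disease	I86.4	3
severe_liver_disease	K70.4	3
severe_liver_disease	K71.1	3
severe_liver_disease	K72.1	3
severe_liver_disease	K72.9	3
severe_liver_disease	K76.5	3
severe_liver_disease	K76.6	3
severe_liver_disease	K76.7	3
metastatic_solid_tumor	C77	6
metastatic_solid_tumor	C78	6
metastatic_solid_tumor	C79	6
metastatic_solid_tumor	C80	6
aids_hiv	B20	6
aids_hiv	B21	6
aids_hiv	B22	6
aids_hiv	B24	6
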