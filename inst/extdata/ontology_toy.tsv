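system	prefix	group	description
ICD10	I10	hypertensive_diseases	Essential hypertension
ICD10	I11	hypertensive_diseases	Hypertensive heart disease
ICD10	I12	hypertensive_diseases	Hypertensive CKD
ICD10	I13	hypertensive_diseases	Hypertensive heart and CKD
ICD10	I15	hypertensive_diseases	Secondary hypertension
ICD10	I16	hypertensive_diseases	Hypertensive crisis
ICD10	I20	ischemic_heart_diseases	Angina pectoris
ICD10	I21	ischemic_heart_diseases	Acute myocardial infarction
ICD10	I22	ischemic_heart_diseases	Subsequent myocardial infarction
ICD10	I23	ischemic_heart_diseases	Complications following MI
ICD10	I24	ischemic_heart_diseases	Other acute IHD
ICD10	I25	ischemic_heart_diseases	Chronic IHD
ICD10	E08	diabetes_mellitus	Diabetes due to underlying condition
ICD10	E09	diabetes_mellitus	Drug-induced diabetes
ICD10	E10	diabetes_mellitus	Type 1 diabetes
ICD10	E11	diabetes_mellitus	Type 2 diabetes
ICD10	E13	diabetes_mellitus	Other specified diabetes
ICD10	N17	renal_failure	Acute kidney failure
ICD10	N18	renal_failure	Chronic kidney disease
ICD10	N19	renal_failure	Unspecified kidney failure
ICD10	J40	chronic_lower_respiratory	Bronchitis
ICD10	J41	chronic_lower_respiratory	Simple chronic bronchitis
ICD10	J42	chronic_lower_respiratory	Unspecified chronic bronchitis
ICD10	J43	chronic_lower_respiratory	Emphysema
ICD10	J44	chronic_lower_respiratory	COPD
ICD10	J45	chronic_lower_respiratory	Asthma
ICD10	J47	chronic_lower_respiratory	Bronchiectasis
ICD10	R00	circulatory_respiratory_symptoms	Abnormal heart beat
ICD10	R03	circulatory_respiratory_symptoms	Abnormal blood pressure reading
ICD10	R06	circulatory_respiratory_symptoms	Abnormal breathing
ICD10	R07	circulatory_respiratory_symptoms	Chest pain
ICD10	R09	circulatory_respiratory_symptoms	Other circulatory/respiratory symptoms
CPT	992	evaluation_and_management	Office/outpatient visits
CPT	993	evaluation_and_management	Hospital/consult visits
CPT	800	laboratory_panels	Organ or disease panels
CPT	8061	laboratory_panels	Lipid panel
CPT	930	cardiography	ECG and cardiography services
DRUG	atorvastatin	C10_lipid_modifying	Statin
DRUG	simvastatin	C10_lipid_modifying	Statin
DRUG	rosuvastatin	C10_lipid_modifying	Statin
DRUG	lisinopril	C09_ras_agents	ACE inhibitor
DRUG	losartan	C09_ras_agents	Angiotensin receptor blocker
DRUG	furosemide	C03_diuretics	Loop diuretic
DRUG	hydrochlorothiazide	C03_diuretics	Thiazide diuretic
DRUG	metformin	A10_antidiabetics	Biguanide
DRUG	insulin	A10_antidiabetics	Insulin
DRUG	aspirin	B01_antithrombotics	Platelet aggregation inhibitor
DRUG	clopidogrel	B01_antithrombotics	Platelet aggregation inhibitor
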