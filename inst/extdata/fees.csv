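service_name,code,payer_group,points,unit_price,frequency_role
Flat rate coverage per quarter,GOP 03000,general_practitioner,157,16.99,per_quarter_gp
Chronic illness surcharge on GOP 03000,GOP 03220,general_practitioner,130,14.07,per_quarter_gp
Additional surcharge on GOP 03220,GOP 03222,general_practitioner,10,1.08,per_quarter_gp
Detailed conversation,GOP 04230,general_practitioner,90,9.74,per_quarter_gp
Retainer fee once per quarter,GOP 03040,general_practitioner,144,15.58,per_quarter_gp
Pneumological consultation 60 years and above,GOP 13642,pneumologist,210,22.73,per_quarter_pneumo
Pneumologist surcharge once per quarter,GOP 13644,pneumologist,41,4.44,per_quarter_pneumo
Bronchoscopy,GOP 13662,pneumologist,988,106.93,once
Bronchoalveolar lavage surcharge on GOP 13662,GOP 13663,pneumologist,242,26.19,once
ECG,EBM 27320,methods,NA,0.00,zero_billable
Audiometry,OPS 09320,methods,147,15.91,per_audiometry
X-ray chest,EBM 34241,methods,152,16.45,per_xray
Ophthalmologic consultation,EBM 06212,methods,150,16.23,per_ophtha_visit
Computerized tomography,EBM 34330,methods,660,71.43,per_ct
Surcharge contrast agent,EBM 34345,methods,228,24.68,per_ct
Microscopy test for mycobacteria,EBM 32176,microbiology,NA,5.20,per_sputum_sample
Nucleic acid amplification test,EBM 32825,microbiology,NA,61.40,once
Culture test for mycobacteria per material,EBM 32747,microbiology,NA,34.90,per_sputum_sample
Differentiation of mycobacteria,EBM 32764,microbiology,NA,28.40,once
Resistance definition per mycobacteria type,EBM 32770,microbiology,NA,39.50,once
Anti-HBc,EBM 32614,laboratory,NA,5.90,once
HBs-Ag,EBM 32781,laboratory,NA,5.50,once
Chloride,EBM 32084,laboratory,NA,0.25,per_lab_visit
Sodium,EBM 32083,laboratory,NA,0.25,per_lab_visit
Potassium,EBM 32081,laboratory,NA,0.25,per_lab_visit
Calcium,EBM 32082,laboratory,NA,0.25,per_lab_visit
Creatinine (Jaffe method),EBM 32066,laboratory,NA,0.25,per_lab_visit
Urea,EBM 32065,laboratory,NA,0.25,per_lab_visit
Blood count,EBM 32122,laboratory,NA,1.10,per_lab_visit
Bilirubin total,EBM 32058,laboratory,NA,0.25,per_lab_visit
Gamma-glutamyl transferase,EBM 32071,laboratory,NA,0.25,per_lab_visit
Glutamate-oxaloacetate transaminase,EBM 32069,laboratory,NA,0.25,per_lab_visit
Glutamate-pyruvate transaminase,EBM 32070,laboratory,NA,0.25,per_lab_visit
C-reactive protein,EBM 32460,laboratory,NA,4.90,per_lab_visit
Amikacin serum level,EBM 32341,laboratory,NA,17.70,per_amk_level
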