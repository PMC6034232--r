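item,description,code,cost_eur,reference
ct,CT examination (abdomen),88.01.5,137.23,Regional Healthcare Service price list
first_visit,First oncology visit,89.7B.6,22.50,Regional Healthcare Service price list
control_visit,Control visit,89.01.F,17.90,Regional Healthcare Service price list
blood_count,Blood count,90.62.2,4.05,Regional Healthcare Service price list
creatinine,Creatinine,90.16.3,1.70,Regional Healthcare Service price list
sodium,Sodium,90.40.4,1.70,Regional Healthcare Service price list
potassium,Potassium,90.37.4,1.70,Regional Healthcare Service price list
calcium,Calcium,90.11.4,1.70,Regional Healthcare Service price list
prothrombin_time,Prothrombin time,90.75.4,2.60,Regional Healthcare Service price list
albumin,Albumin,90.05.1,2.90,Regional Healthcare Service price list
bilirubin,Bilirubin,90.10.4,1.70,Regional Healthcare Service price list
alpha_fetoprotein,Alpha-fetoprotein,90.05.5,11.05,Regional Healthcare Service price list
alt,Alanine aminotransferase,90.04.5,1.70,Regional Healthcare Service price list
ggt,Gamma-glutamyl transpeptidase,90.25.5,1.70,Regional Healthcare Service price list
alkaline_phosphatase,Alkaline phosphatase,90.23.5,1.70,Regional Healthcare Service price list
sorafenib_monthly,Sorafenib monthly hospital cost,,3787,Monthly hospital cost
tare_simulation,TARE procedure simulation,DRG203,4052,Regional DRG reimbursement
tare,TARE procedure,DRG409,9510,Regional DRG reimbursement
tace,TACE procedure,DRG203,4052,Regional DRG reimbursement
rfa_pei_resection,RFA/PEI or liver resection,DRG192,7549,Regional DRG reimbursement
radiotherapy,Radiotherapy,DRG409,4041,Regional DRG reimbursement
decompensation_hosp,Hospitalization for liver decompensation,DRG464,1688,Regional DRG reimbursement
transplant,Liver transplantation,DRG480,68027,Regional DRG reimbursement
transplant_yearly,Yearly cost after liver transplantation,,6229,Camma 2013 uplifted to 2018
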