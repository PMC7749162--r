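source_id	preferred_name	identifier
MEDDRA	Alzheimer Disease	MDR:000007
MEDDRA	Asthma	MDR:000003
MEDDRA	Atopic Dermatitis	MDR:000021
MEDDRA	Chronic Kidney Disease	MDR:000029
MEDDRA	Chronic Obstructive Pulmonary Disease	MDR:000011
MEDDRA	Colorectal Neoplasms	MDR:000035
MEDDRA	Diabetes Mellitus	MDR:000001
MEDDRA	HIV Infections	MDR:000025
MEDDRA	Leukemia	MDR:000031
MEDDRA	Lung Neoplasms	MDR:000005
MEDDRA	Melanoma	MDR:000033
MEDDRA	Multiple Sclerosis	MDR:000019
MEDDRA	Myocardial Infarction	MDR:000013
MEDDRA	Obesity	MDR:000015
MEDDRA	Ovarian Neoplasms	MDR:000037
MEDDRA	Rheumatoid Arthritis	MDR:000009
MEDDRA	Schizophrenia	MDR:000017
MEDDRA	Sickle Cell Disease	MDR:000039
MEDDRA	Tuberculosis	MDR:000027
MEDDRA	Ulcerative Colitis	MDR:000023
MESH	Acetaminophen	D:000052
MESH	Alzheimer Disease	D:000007
MESH	Amlodipine	D:000046
MESH	Anemia	D:000030
MESH	Anxiety Disorders	D:000016
MESH	Aspirin	D:000041
MESH	Asthma	D:000003
MESH	Atopic Dermatitis	D:000021
MESH	Atorvastatin	D:000044
MESH	BCG Vaccine	D:000062
MESH	Breast Neoplasms	D:000004
MESH	Cardiac Pacemaker	D:000064
MESH	Chronic Kidney Disease	D:000029
MESH	Chronic Obstructive Pulmonary Disease	D:000011
MESH	Cisplatin	D:000059
MESH	Cognitive Behavioral Therapy	D:000066
MESH	Colorectal Neoplasms	D:000035
MESH	Coronary Stent	D:000065
MESH	Crohn Disease	D:000022
MESH	Cystic Fibrosis	D:000038
MESH	Depressive Disorder	D:000006
MESH	Diabetes Mellitus	D:000001
MESH	Epilepsy	D:000018
MESH	Exercise Program	D:000067
MESH	Fluoxetine	D:000049
MESH	Gabapentin	D:000050
MESH	Gene Transfer Therapy	D:000071
MESH	HIV Infections	D:000025
MESH	Hepatitis C	D:000024
MESH	Hypertension	D:000002
MESH	Ibuprofen	D:000051
MESH	Insulin	D:000043
MESH	Insulin Pump	D:000063
MESH	Leukemia	D:000031
MESH	Lisinopril	D:000045
MESH	Lymphoma	D:000032
MESH	Magnetic Resonance Imaging	D:000074
MESH	Malaria	D:000028
MESH	Metformin	D:000042
MESH	Myocardial Infarction	D:000013
MESH	Obesity	D:000015
MESH	Omega-3 Supplement	D:000073
MESH	Osteoarthritis	D:000010
MESH	Ovarian Neoplasms	D:000037
MESH	Paclitaxel	D:000060
MESH	Pancreatic Neoplasms	D:000036
MESH	Parkinson Disease	D:000008
MESH	Pembrolizumab	D:000058
MESH	Placebo	D:000076
MESH	Prednisone	D:000053
MESH	Prostatic Neoplasms	D:000034
MESH	Proton Beam Therapy	D:000070
MESH	Psoriasis	D:000020
MESH	Radiotherapy	D:000069
MESH	Rheumatoid Arthritis	D:000009
MESH	Rituximab	D:000056
MESH	Schizophrenia	D:000017
MESH	Sertraline	D:000048
MESH	Sickle Cell Disease	D:000039
MESH	Stroke	D:000014
MESH	Trastuzumab	D:000057
MESH	Tuberculosis	D:000027
MESH	Ulcerative Colitis	D:000023
MESH	Vitamin D Supplement	D:000072
MESH	Warfarin	D:000055
SNOMEDCT	Albuterol	SCT:000054
SNOMEDCT	Aspirin	SCT:000041
SNOMEDCT	Atorvastatin	SCT:000044
SNOMEDCT	BCG Vaccine	SCT:000062
SNOMEDCT	Chronic Kidney Disease	SCT:000029
SNOMEDCT	Chronic Obstructive Pulmonary Disease	SCT:000011
SNOMEDCT	Cisplatin	SCT:000059
SNOMEDCT	Colorectal Neoplasms	SCT:000035
SNOMEDCT	Computed Tomography	SCT:000075
SNOMEDCT	Coronary Stent	SCT:000065
SNOMEDCT	Cystic Fibrosis	SCT:000038
SNOMEDCT	Dietary Counseling	SCT:000068
SNOMEDCT	Gabapentin	SCT:000050
SNOMEDCT	Gene Transfer Therapy	SCT:000071
SNOMEDCT	Heart Failure	SCT:000012
SNOMEDCT	Hypertension	SCT:000002
SNOMEDCT	Influenza	SCT:000026
SNOMEDCT	Influenza Vaccine	SCT:000061
SNOMEDCT	Lung Neoplasms	SCT:000005
SNOMEDCT	Lymphoma	SCT:000032
SNOMEDCT	Magnetic Resonance Imaging	SCT:000074
SNOMEDCT	Melanoma	SCT:000033
SNOMEDCT	Migraine Disorders	SCT:000040
SNOMEDCT	Multiple Sclerosis	SCT:000019
SNOMEDCT	Omeprazole	SCT:000047
SNOMEDCT	Parkinson Disease	SCT:000008
SNOMEDCT	Prednisone	SCT:000053
SNOMEDCT	Psoriasis	SCT:000020
SNOMEDCT	Rituximab	SCT:000056
SNOMEDCT	Schizophrenia	SCT:000017
SNOMEDCT	Stroke	SCT:000014
SNOMEDCT	Ulcerative Colitis	SCT:000023
MESH	Aspirin	D:900001
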