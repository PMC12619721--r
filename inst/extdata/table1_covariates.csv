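sample_id,pmi_hours,sex,age_years,site,cause,proof_of_concept,in_extended
1,16,F,31,CA,Haemorragic Shock,TRUE,TRUE
2,20,M,20,CA,Mechanical Asphyxia (Hanging),TRUE,TRUE
3,25,M,35,CA,Acute Cardiac Failure,TRUE,TRUE
4,32,M,21,CA,Epidural Hematoma,TRUE,TRUE
5,33,M,87,CA,Subdural Hematoma,TRUE,TRUE
6,33.5,F,52,CA,Cardiogenic Shock (Myocardial Infarction),TRUE,FALSE
7,38,M,68,CA,Haemorrhagic and Traumatic Shock,TRUE,TRUE
8,39,M,63,CA,Mechanical Asphyxia (Positional),TRUE,TRUE
9,41,F,81,CA,Acute Cardiac Failure,TRUE,TRUE
10,46,M,32,CA,Drug Intoxication (Cocaine),TRUE,TRUE
11,46,M,38,CA,Mechanical Asphyxia (Hanging),TRUE,TRUE
12,62,F,60,CA,Pulmonary Embolism and Cerebellar Ischemia,TRUE,TRUE
13,63,M,42,CA,Cerebral Ischemia,TRUE,TRUE
14,66,M,37,CA,Haemorragic Shock,TRUE,TRUE
15,70.3,M,49,CA,Mechanical Asphyxia (Aspiration),TRUE,TRUE
16,77,F,39,CA,Multiorgan Failure,TRUE,TRUE
17,82,M,28,CA,"Drug Intoxication (Cocaine, Heroin)",TRUE,TRUE
18,86,M,58,CA,Acute Bowel Infarction,TRUE,TRUE
19,92,M,32,CA,Hypoxic Brain Death,TRUE,TRUE
20,100,M,81,CA,Haemorrhagic Shock,TRUE,TRUE
21,120,F,77,CA,Neoplastic Cachexia,TRUE,TRUE
22,160,M,42,CA,Drug Intoxication (Buprenorphine),TRUE,TRUE
23,168,F,69,CA,Neoplastic Cachexia,TRUE,TRUE
24,170,M,80,CA,Acute Cardiac Failure,TRUE,TRUE
25,106,M,87,CA,Traumatic Shock,FALSE,TRUE
26,55.5,M,28,CA,Acute Cardiac Failure,FALSE,TRUE
27,70,F,71,CA,Acute Cardiac Failure,FALSE,TRUE
28,47,M,15,CA,Traumatic Brain Injury,FALSE,TRUE
29,54,M,20,CA,Haemorrhagic Shock,FALSE,TRUE
30,45,M,72,CA,Acute Cardiac Failure,FALSE,TRUE
31,104,M,81,CA,Septic Shock,FALSE,TRUE
32,64,M,59,CA,Traumatic Brain Injury,FALSE,TRUE
33,65,M,21,CA,Traumatic Shock,FALSE,TRUE
34,69.5,M,37,CA,Acute Cardiac Failure,FALSE,TRUE
35,85,M,73,CA,Haemorragic Shock in Aneurismatic Rupture,FALSE,TRUE
36,96,M,48,CA,Traumatic Shock,FALSE,TRUE
37,48,M,30,CA,Mechanical Asphyxia (Aspiration),FALSE,TRUE
38,110,F,35,CA,Septic Shock in Intestinal Perforation,FALSE,TRUE
39,93,F,66,CA,Acute Cardiac Failure,FALSE,TRUE
40,47,F,29,CA,Acute Cardiac Failure,FALSE,TRUE
41,78,F,41,CA,Traumatic Shock,FALSE,TRUE
42,53,M,52,CA,Traumatic Shock,FALSE,TRUE
43,53,M,35,CA,Traumatic Shock,FALSE,TRUE
44,75,F,45,RM,Traumatic Shock,FALSE,TRUE
45,141,M,62,RM,Traumatic Shock,FALSE,TRUE
46,63,M,59,RM,Acute Cardiac Failure,FALSE,TRUE
47,130,F,55,RM,Multiorgan Failure in Renal Carcinoma,FALSE,TRUE
48,74,F,78,RM,Traumatic Shock,FALSE,TRUE
49,170,F,74,RM,Traumatic Shock,FALSE,TRUE
50,60,M,53,RM,Mechanical Asphyxia (Hanging),FALSE,TRUE
51,39,M,48,RM,Acute Cardiac Failure,FALSE,TRUE
52,199,M,44,RM,Multiorgan Failure in COVID-19,FALSE,TRUE
53,36,M,23,RM,Traumatic Shock,FALSE,TRUE
54,54,F,39,RM,Acute Cardiac Failure,FALSE,TRUE
55,125,F,85,RM,Acute Cardiac Failure,FALSE,TRUE
56,31,F,24,RM,Acute Cardiac Failure,FALSE,TRUE
57,42,F,45,RM,Traumatic Shock,FALSE,TRUE
58,154,M,44,RM,"Drug Intoxication (Cocaine, Heroin)",FALSE,TRUE
59,73.5,M,82,RM,Mechanical Asphyxia (Hanging),FALSE,TRUE
60,97,F,57,RM,Caustic Aspiration,FALSE,TRUE
61,105,M,81,RM,Acute Cardiac Failure,FALSE,TRUE
62,70.5,M,65,RM,Acute Cardiac Failure,FALSE,TRUE
63,168,M,75,RM,Acute Cardiac Failure,FALSE,TRUE
64,26.5,F,54,RM,Mechanical Asphyxia (Hanging),FALSE,TRUE
65,73,M,51,RM,Mechanical Asphyxia (Hanging),FALSE,TRUE
66,32,M,80,RM,Acute Cardiac Failure,FALSE,TRUE
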