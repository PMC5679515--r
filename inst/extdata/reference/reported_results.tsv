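ade	total	tp	tn	precision	sensitivity	specificity	accuracy	f_measure
Agitation	221	142	32	0.89	0.83	0.65	0.79	0.86
Akathisia	215	132	64	0.96	0.90	0.93	0.91	0.93
Arrhythmia	232	129	61	0.88	0.85	0.77	0.82	0.86
Cardiomyopathy	204	55	109	0.79	0.68	0.88	0.80	0.73
Constipation	475	315	99	0.91	0.91	0.76	0.87	0.91
Convulsions	148	84	37	0.92	0.81	0.84	0.82	0.86
Diarrhoea	221	140	55	0.93	0.90	0.83	0.88	0.92
Dizziness	234	130	96	0.94	0.83	0.90	0.85	0.88
Dry Mouth	211	124	56	0.91	0.87	0.82	0.85	0.89
Galactorrhea	139	68	50	0.83	0.91	0.78	0.85	0.87
Hypersalivation	193	161	18	0.97	0.95	0.78	0.93	0.96
Insomnia	189	119	38	0.84	0.93	0.62	0.83	0.88
Myocarditis	188	40	96	0.51	0.75	0.71	0.72	0.61
Nausea	369	241	75	0.95	0.86	0.88	0.90	0.92
Pneumonia	173	81	75	0.89	0.94	0.93	0.90	0.92
Sedation	189	108	54	0.89	0.89	0.81	0.86	0.89
SJS	333	68	205	0.60	0.88	0.82	0.82	0.72
Tachycardia	230	192	13	0.96	0.91	0.65	0.89	0.94
Weight Gain	209	108	51	0.92	0.87	0.82	0.86	0.90
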