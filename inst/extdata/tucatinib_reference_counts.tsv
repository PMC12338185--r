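characteristic	category	count	printed_percent
report_year	2020	487	25.50
report_year	2021	536	28.06
report_year	2022	275	14.40
report_year	2023	217	11.36
report_year	2024	395	20.68
sex	Female	1853	97.02
sex	Male	24	1.26
sex	Unknown	33	1.73
age_group	<18	1	0.05
age_group	18-44	140	7.33
age_group	45-59	292	15.29
age_group	60-74	281	14.71
age_group	75-89	42	2.20
age_group	>=90	0	0.00
age_group	Unknown	1154	60.42
reporter	Physician	926	48.48
reporter	Consumer	644	33.72
reporter	Pharmacist	339	17.75
reporter	Unknown	1	0.05
country	United States	1533	80.26
country	Other	377	19.74
outcomes	Other serious	679	43.03
outcomes	Hospitalization	650	41.19
outcomes	Death	227	14.39
outcomes	Disability	12	0.76
outcomes	Life threatening	7	0.44
outcomes	Congenital anomaly	3	0.19
onset_bucket	<7	66	11.36
onset_bucket	7-28	86	14.80
onset_bucket	28-60	55	9.47
onset_bucket	>=60	106	18.24
onset_bucket	Unknown	268	46.13
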