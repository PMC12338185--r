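pt	soc
Diarrhoea	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Stomatitis	Gastrointestinal disorders
Dyspepsia	Gastrointestinal disorders
Palmar-plantar erythrodysaesthesia syndrome	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Skin discoloration	Skin and subcutaneous tissue disorders
Paronychia	Skin and subcutaneous tissue disorders
Hepatic enzyme increased	Investigations
Aspartate aminotransferase increased	Investigations
Blood bilirubin increased	Investigations
Ejection fraction decreased	Investigations
Fatigue	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Peripheral neuropathy	Nervous system disorders
Memory impairment	Nervous system disorders
Anaemia	Blood and lymphatic system disorders
Insomnia	Psychiatric disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Decreased appetite	Metabolism and nutrition disorders
Dehydration	Metabolism and nutrition disorders
Hypokalaemia	Metabolism and nutrition disorders
Hepatotoxicity	Hepatobiliary disorders
Jaundice	Hepatobiliary disorders
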