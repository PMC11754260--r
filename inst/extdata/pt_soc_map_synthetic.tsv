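pt	soc
Dysphonia	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Aphonia	Respiratory, thoracic and mediastinal disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Wheezing	Respiratory, thoracic and mediastinal disorders
Throat irritation	Respiratory, thoracic and mediastinal disorders
Vocal cord disorder	Respiratory, thoracic and mediastinal disorders
Pharyngeal erythema	Respiratory, thoracic and mediastinal disorders
Asthma	Respiratory, thoracic and mediastinal disorders
Device use issue	Injury, poisoning and procedural complications
Wrong technique in product usage process	Injury, poisoning and procedural complications
Product use issue	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Lip injury	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Medication error	Injury, poisoning and procedural complications
Pneumonia	Infections and infestations
Candida infection	Infections and infestations
Oral candidiasis	Infections and infestations
Nasopharyngitis	Infections and infestations
Urinary tract infection	Infections and infestations
Influenza	Infections and infestations
Bronchitis	Infections and infestations
Sinusitis	Infections and infestations
Nausea	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Dry mouth	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Dysphagia	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Oral mucosal exfoliation	Gastrointestinal disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Tremor	Nervous system disorders
Somnolence	Nervous system disorders
Dysgeusia	Nervous system disorders
Migraine	Nervous system disorders
Palpitations	Cardiac disorders
Tachycardia	Cardiac disorders
Atrial fibrillation	Cardiac disorders
Angina pectoris	Cardiac disorders
Myocardial infarction	Cardiac disorders
Hypertension	Vascular disorders
Hypotension	Vascular disorders
Aneurysm	Vascular disorders
Arteriosclerosis	Vascular disorders
Deep vein thrombosis	Vascular disorders
Fatigue	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Chest discomfort	General disorders and administration site conditions
Oedema peripheral	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Pain	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Death	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Chest pain	General disorders and administration site conditions
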