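pt	soc
somnolence	nervous system disorders
dizziness	nervous system disorders
headache	nervous system disorders
nausea	gastrointestinal disorders
vomiting	gastrointestinal disorders
fatigue	general disorders and administration site conditions
drug ineffective	general disorders and administration site conditions
anxiety	psychiatric disorders
insomnia	psychiatric disorders
depression	psychiatric disorders
tremor	nervous system disorders
diarrhoea	gastrointestinal disorders
rash	skin and subcutaneous tissue disorders
dyspnoea	respiratory, thoracic and mediastinal disorders
hypertension	vascular disorders
fall	injury, poisoning and procedural complications
pyrexia	general disorders and administration site conditions
pain	general disorders and administration site conditions
sopor	psychiatric disorders
confusional state	psychiatric disorders
sedation	nervous system disorders
palpitations	cardiac disorders
pruritus	skin and subcutaneous tissue disorders
constipation	gastrointestinal disorders
weight increased	investigations
asthenia	general disorders and administration site conditions
myalgia	musculoskeletal and connective tissue disorders
cough	respiratory, thoracic and mediastinal disorders
drug abuse	psychiatric disorders
suicide attempt	psychiatric disorders
delirium	psychiatric disorders
psychotic disorder	psychiatric disorders
hallucination	psychiatric disorders
memory impairment	nervous system disorders
muscle rigidity	musculoskeletal and connective tissue disorders
respiratory depression	respiratory, thoracic and mediastinal disorders
decreased appetite	metabolism and nutrition disorders
chills	general disorders and administration site conditions
oedema peripheral	general disorders and administration site conditions
hyperhidrosis	skin and subcutaneous tissue disorders
neuroleptic malignant syndrome	nervous system disorders
seizure	nervous system disorders
catatonia	psychiatric disorders
bradyphrenia	psychiatric disorders
sinus tachycardia	cardiac disorders
pericarditis	cardiac disorders
atelectasis	respiratory, thoracic and mediastinal disorders
pneumonia aspiration	infections and infestations
muscle injury	injury, poisoning and procedural complications
acute kidney injury	renal and urinary disorders
obesity	metabolism and nutrition disorders
hypercholesterolaemia	metabolism and nutrition disorders
pemphigus	skin and subcutaneous tissue disorders
folliculitis	infections and infestations
urinary tract infection	infections and infestations
duodenal ulcer perforation	gastrointestinal disorders
deep vein thrombosis postoperative	vascular disorders
c-reactive protein abnormal	investigations
blood pressure increased	investigations
anaemia	blood and lymphatic system disorders
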