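raw	canonical
LORAZEPAM	lorazepam
Ativan	lorazepam
lorazepam tab	lorazepam
DIAZEPAM	diazepam
Valium	diazepam
ALPRAZOLAM	alprazolam
Xanax	alprazolam
SERTRALINE	sertraline
Zoloft	sertraline
METFORMIN	metformin
Glucophage	metformin
ATORVASTATIN	atorvastatin
Lipitor	atorvastatin
IBUPROFEN	ibuprofen
Advil	ibuprofen
OMEPRAZOLE	omeprazole
Prilosec	omeprazole
AMOXICILLIN	amoxicillin
Amoxil	amoxicillin
LISINOPRIL	lisinopril
Zestril	lisinopril
ADALIMUMAB	adalimumab
Humira	adalimumab
PARACETAMOL	paracetamol
Tylenol	paracetamol
acetaminophen	paracetamol
lorazepam	lorazepam
diazepam	diazepam
alprazolam	alprazolam
sertraline	sertraline
metformin	metformin
atorvastatin	atorvastatin
ibuprofen	ibuprofen
omeprazole	omeprazole
amoxicillin	amoxicillin
lisinopril	lisinopril
adalimumab	adalimumab
paracetamol	paracetamol
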