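surface	canonical
agitation	agitation
agitated	agitation
akathisia	akathisia
akathisic	akathisia
acathisia	akathisia
arrhythmia	arrhythmia
arrhythmias	arrhythmia
arrythmia	arrhythmia
irregular heart beat	arrhythmia
irregular heartbeat	arrhythmia
galactorrhoea	galactorrhoea
galactorrhea	galactorrhoea
nausea	nausea
nauseous	nausea
nauseated	nausea
feeling sick	nausea
felt sick	nausea
myocarditis	myocarditis
cardiomyopathy	cardiomyopathy
constipation	constipation
constipated	constipation
convulsion	convulsions
convulsions	convulsions
seizure	convulsions
seizures	convulsions
convulsing	convulsions
diarrhoea	diarrhoea
diarrhea	diarrhoea
loose stools	diarrhoea
dizziness	dizziness
dizzy	dizziness
light-headed	dizziness
lightheaded	dizziness
light-headedness	dizziness
lightheadedness	dizziness
giddy	dizziness
giddiness	dizziness
dry mouth	dry mouth
xerostomia	dry mouth
mouth dryness	dry mouth
hypersalivation	hypersalivation
drooling	hypersalivation
excessive salivation	hypersalivation
sialorrhoea	hypersalivation
sialorrhea	hypersalivation
pneumonia	pneumonia
chest infection	pneumonia
sedation	sedation
sedated	sedation
sleepy	sedation
sleepiness	sedation
drowsy	sedation
drowsiness	sedation
somnolence	sedation
somnolent	sedation
stevens-johnson syndrome	sjs
stevens johnson syndrome	sjs
steven johnson syndrome	sjs
sjs	sjs
tachycardia	tachycardia
tachycardic	tachycardia
racing heart	tachycardia
heart racing	tachycardia
weight gain	weight gain
gained weight	weight gain
gaining weight	weight gain
putting on weight	weight gain
put on weight	weight gain
weight increase	weight gain
insomnia	insomnia
sleeplessness	insomnia
poor sleep	insomnia
headache	headache
headaches	headache
head ache	headache
restlessness	restlessness
restless	restlessness
anxiety	anxiety
anxious	anxiety
anxiousness	anxiety
fainting	fainting
fainted	fainting
syncope	fainting
blackout	fainting
blackouts	fainting
disorientation	disorientation
disorientated	disorientation
disoriented	disorientation
irritability	irritability
irritable	irritability
vomiting	vomiting
vomited	vomiting
emesis	vomiting
throwing up	vomiting
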