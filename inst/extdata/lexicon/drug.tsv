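surface	canonical
medication	medication
medications	medications
medicine	medicine
medicines	medicines
meds	meds
tablet	tablet
tablets	tablets
drug	drug
drugs	drugs
antipsychotic	antipsychotic
antipsychotics	antipsychotics
antidepressant	antidepressant
antidepressants	antidepressants
mood stabiliser	mood stabiliser
mood stabilizer	mood stabilizer
hypnotic	hypnotic
anxiolytic	anxiolytic
beta-blocker	beta-blocker
beta blocker	beta blocker
beta-blockers	beta-blockers
depot	depot
depot injection	depot injection
olanzapine	olanzapine
olanzapin	olanzapine
clozapine	clozapine
clozapin	clozapine
risperidone	risperidone
quetiapine	quetiapine
quetiapin	quetiapine
aripiprazole	aripiprazole
haloperidol	haloperidol
amisulpride	amisulpride
paliperidone	paliperidone
lurasidone	lurasidone
chlorpromazine	chlorpromazine
flupentixol	flupentixol
zuclopenthixol	zuclopenthixol
sertraline	sertraline
fluoxetine	fluoxetine
citalopram	citalopram
escitalopram	escitalopram
paroxetine	paroxetine
venlafaxine	venlafaxine
duloxetine	duloxetine
mirtazapine	mirtazapine
amitriptyline	amitriptyline
clomipramine	clomipramine
nortriptyline	nortriptyline
trazodone	trazodone
lithium	lithium
sodium valproate	sodium valproate
valproate	valproate
carbamazepine	carbamazepine
lamotrigine	lamotrigine
lorazepam	lorazepam
diazepam	diazepam
clonazepam	clonazepam
zopiclone	zopiclone
zolpidem	zolpidem
promethazine	promethazine
pregabalin	pregabalin
propranolol	propranolol
procyclidine	procyclidine
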