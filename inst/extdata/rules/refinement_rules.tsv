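rule_id	action	category	scope	type	pattern	description
RET-01	retain	B	clause	tokens	<ade> ..3 <negation> ..1 worsened|worse|worsening|deteriorated|escalated|exacerbated	negated change-of-state verb: the ADE has not worsened, so it is present
RET-02	retain	B	clause	tokens	<negation> ..1 increase|increased|worsening|deterioration|escalation|exacerbation ..1 in|of ..1 <ade>	no increase in the ADE: present at prior level
RET-03	retain	B	clause	tokens	<ade> ..3 <negation> ..1 settled|resolved|subsided|abated|improved|eased	ADE has not settled/resolved: still present
RET-04	retain	B	clause	tokens	<negation> ..1 improvement|relief|reduction|change ..1 in|of ..1 <ade>	no improvement in the ADE: still present
RET-05	retain	B	clause	tokens	<ade> ..2 <negation> ..1 controlled|managed|tolerated|responding	ADE not controlled: still present
RET-06	retain	A	clause	tokens	<negation> ..2 <administration> ..3 <drug>	negation scopes over drug administration, not the ADE
RET-07	retain	A	clause	tokens	<negation> ..1 compliant|adherent|adherence|compliance	negation of medication compliance, not of the ADE
RET-08	retain	A	clause	tokens	<negation> ..1 <administration> ..2 dose|doses|dosage	negation of dosing, not of the ADE
RET-09	retain	A	clause	tokens	<negation> ..1 tolerating|tolerate|tolerated ..3 <drug>	negation of drug tolerance: the ADE is present
REM-01	remove	a	clause	tokens	<monitoring> ..4 <ade>	monitoring/screening language around the ADE
REM-02	remove	a	clause	tokens	warn|warns|warned|warning ..4 <ade>	warning given about a potential ADE
REM-03	remove	a	clause	tokens	<drug_link> ..3 <ade>	drug-can-cause explanation of a potential ADE
REM-04	remove	a	clause	tokens	<ade> ..4 investigation|investigations|investigated	ADE under ongoing investigation
REM-05	remove	a	clause	tokens	risk|risks ..3 <ade>	risk discussion of a potential ADE
REM-06	remove	a	clause	tokens	explained|discussed|advised|informed|counselled ..5 <ade>	explanation/advice about a potential ADE
REM-07	remove	a	clause	tokens	<negative_effect> ..2 include|includes|including ..3 <ade>	side-effect list enumeration
REM-08	remove	a	clause	tokens	leaflet|literature|information ..4 <ade>	information material about a potential ADE
REM-09	remove	b	clause	tokens	unstable|uncertain|unclear|equivocal|questionable ..2 <ade>	uncertainty qualifier adjacent to the ADE
REM-10	remove	b	clause	tokens	query|queried|querying ..1 <ade>	query prefix: uncertain ADE
REM-11	remove	b	sentence	regex_after	^\s{0,2}\?	question mark immediately after the ADE
REM-12	remove	b	clause	tokens	differential|differentials ..4 <ade>	ADE named in a differential diagnosis
REM-13	remove	b	clause	tokens	cannot|unable ..1 exclude|rule ..2 <ade>	ADE cannot be excluded: uncertain
REM-21	remove	d	sentence	email		ADE inside an email address
REM-22	remove	d	sentence	url		ADE inside a URL
REM-23	remove	d	sentence	caps_run		ADE inside an all-capitals organisation name
REM-14	remove	c	sentence	regex	\*\s*no\s*\*\s*yes	questionnaire checkbox pattern (*No * Yes)
REM-15	remove	c	sentence	regex	\b(?:yes\s*/\s*no|y\s*/\s*n)\b	questionnaire yes/no choice
REM-16	remove	c	sentence	regex	\bx\s*[0-9]+\b	questionnaire trailing score (x N)
REM-17	remove	c	sentence	regex	\[\s*\]|\(\s*\)	empty checkbox brackets
REM-18	remove	c	sentence	slash_adjacent		slash-separated symptom menu item
REM-19	remove	c	sentence	regex	\b(?:please\s+(?:circle|tick|rate)|tick\s+(?:all|one)|circle\s+one)\b	questionnaire instruction line
REM-20	remove	c	sentence	regex	\b(?:questionnaire|rating scale|total score|scored?\s*:)\b	questionnaire or rating-scale context
REM-24	remove	d	clause	tokens	centre|center|clinic|department|unit|service|ward|team ..2 for|of ..3 <ade>	ADE inside an organisational name
REM-25	remove	d	sentence	regex_cs	\b[A-Z]{1,2}[0-9][0-9A-Z]?\s+[0-9][A-Z]{2}\b	ADE in an address line (UK postcode present)
REM-26	remove	d	clause	tokens	<ade> ..1 house|centre|center|clinic|ward|unit|road|street|lane	ADE as part of a place or building name
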