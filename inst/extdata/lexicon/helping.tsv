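surface	canonical	subcategory	case_sensitive
does have	does have	occurrence	0
developed	developed	occurrence	0
develops	develops	occurrence	0
experiencing	experiencing	occurrence	0
has been experiencing	has been experiencing	occurrence	0
suffering from	suffering from	occurrence	0
suffers from	suffers from	occurrence	0
complaining of	complaining of	occurrence	0
complains of	complains of	occurrence	0
presents with	presents with	occurrence	0
presented with	presented with	occurrence	0
noted to have	noted to have	occurrence	0
appeared to be	appeared to be	occurrence	0
appears to be	appears to be	occurrence	0
taking	taking	administration	0
takes	takes	administration	0
took	took	administration	0
taken	taken	administration	0
on	on	administration	0
applying	applying	administration	0
using	using	administration	0
administering	administering	administration	0
administered	administered	administration	0
started	started	administration	0
starting	starting	administration	0
commenced	commenced	administration	0
prescribed	prescribed	administration	0
titrated	titrated	administration	0
stopped	stopped	administration	0
discontinued	discontinued	administration	0
monitor	monitor	monitoring	0
monitoring	monitoring	monitoring	0
monitor for	monitor for	monitoring	0
assess for	assess for	monitoring	0
assessing for	assessing for	monitoring	0
screen for	screen for	monitoring	0
screening for	screening for	monitoring	0
watch for	watch for	monitoring	0
watching for	watching for	monitoring	0
signs of	signs of	monitoring	0
sign of	sign of	monitoring	0
check for	check for	monitoring	0
checking for	checking for	monitoring	0
observe for	observe for	monitoring	0
review for	review for	monitoring	0
look out for	look out for	monitoring	0
alert for	alert for	monitoring	0
side effect	side effect	negative_effect	0
side effects	side effects	negative_effect	0
adverse effect	adverse effect	negative_effect	0
adverse effects	adverse effects	negative_effect	0
adverse reaction	adverse reaction	negative_effect	0
adverse reactions	adverse reactions	negative_effect	0
adverse event	adverse event	negative_effect	0
adverse events	adverse events	negative_effect	0
untoward effect	untoward effect	negative_effect	0
SE	SE	negative_effect	1
EPSE	EPSE	negative_effect	1
as it can be	as it can be	drug_link	0
as it may	as it may	drug_link	0
as it can cause	as it can cause	drug_link	0
as it may cause	as it may cause	drug_link	0
if it cause	if it cause	drug_link	0
if it causes	if it causes	drug_link	0
known for	known for	drug_link	0
may lead	may lead	drug_link	0
may lead to	may lead to	drug_link	0
can lead to	can lead to	drug_link	0
may cause	may cause	drug_link	0
can cause	can cause	drug_link	0
could cause	could cause	drug_link	0
known to cause	known to cause	drug_link	0
may result in	may result in	drug_link	0
can result in	can result in	drug_link	0
may induce	may induce	drug_link	0
can induce	can induce	drug_link	0
associated with	associated with	drug_link	0
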