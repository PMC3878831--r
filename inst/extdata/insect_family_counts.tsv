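species	family	subfamily	count
b_huntii	aldehyde dehydrogenase		5
b_huntii	catalase		2
b_huntii	cytochrome P450		44
b_huntii	cytochrome P450	CYP4	2
b_huntii	cytochrome P450	CYP6	18
b_huntii	thioredoxin/glutaredoxin		2
b_huntii	peroxidase		16
b_huntii	superoxide dismutase		2
b_huntii	acyltransferase		13
b_huntii	glutathione S-transferase		11
b_huntii	glutathione S-transferase	sigma-GST	3
b_huntii	glutathione S-transferase	epsilon-GST	0
b_huntii	sulfotransferase		2
b_huntii	UDP-glucuronosyltransferase		2
b_huntii	acid/alkaline phosphatase		1
b_huntii	amidase		2
b_huntii	aminopeptidase		12
b_huntii	amylase		2
b_huntii	carboxylesterase/esterase		23
b_huntii	glycosidase		8
b_huntii	glucuronidase		1
b_huntii	glycosylase		3
b_huntii	nitrilase		25
b_terrestris	aldehyde dehydrogenase		5
b_terrestris	catalase		1
b_terrestris	cytochrome P450		50
b_terrestris	cytochrome P450	CYP4	6
b_terrestris	cytochrome P450	CYP6	22
b_terrestris	thioredoxin/glutaredoxin		3
b_terrestris	peroxidase		9
b_terrestris	superoxide dismutase		4
b_terrestris	acyltransferase		28
b_terrestris	glutathione S-transferase		14
b_terrestris	glutathione S-transferase	sigma-GST	0
b_terrestris	glutathione S-transferase	epsilon-GST	0
b_terrestris	sulfotransferase		17
b_terrestris	UDP-glucuronosyltransferase		6
b_terrestris	acid/alkaline phosphatase		3
b_terrestris	amidase		4
b_terrestris	aminopeptidase		19
b_terrestris	amylase		1
b_terrestris	carboxylesterase/esterase		17
b_terrestris	glycosidase		7
b_terrestris	glucuronidase		1
b_terrestris	glycosylase		2
b_terrestris	nitrilase		1
b_impatiens	aldehyde dehydrogenase		5
b_impatiens	catalase		2
b_impatiens	cytochrome P450		49
b_impatiens	cytochrome P450	CYP4	5
b_impatiens	cytochrome P450	CYP6	22
b_impatiens	thioredoxin/glutaredoxin		7
b_impatiens	peroxidase		9
b_impatiens	superoxide dismutase		6
b_impatiens	acyltransferase		30
b_impatiens	glutathione S-transferase		15
b_impatiens	glutathione S-transferase	sigma-GST	0
b_impatiens	glutathione S-transferase	epsilon-GST	0
b_impatiens	sulfotransferase		16
b_impatiens	UDP-glucuronosyltransferase		8
b_impatiens	acid/alkaline phosphatase		4
b_impatiens	amidase		8
b_impatiens	aminopeptidase		26
b_impatiens	amylase		1
b_impatiens	carboxylesterase/esterase		22
b_impatiens	glycosidase		8
b_impatiens	glucuronidase		1
b_impatiens	glycosylase		5
b_impatiens	nitrilase		2
a_mellifera	aldehyde dehydrogenase		6
a_mellifera	catalase		6
a_mellifera	cytochrome P450		46
a_mellifera	cytochrome P450	CYP4	5
a_mellifera	cytochrome P450	CYP6	28
a_mellifera	thioredoxin/glutaredoxin		4
a_mellifera	peroxidase		17
a_mellifera	superoxide dismutase		5
a_mellifera	acyltransferase		32
a_mellifera	glutathione S-transferase		18
a_mellifera	glutathione S-transferase	sigma-GST	4
a_mellifera	glutathione S-transferase	epsilon-GST	0
a_mellifera	sulfotransferase		17
a_mellifera	UDP-glucuronosyltransferase		2
a_mellifera	acid/alkaline phosphatase		3
a_mellifera	amidase		4
a_mellifera	aminopeptidase		24
a_mellifera	amylase		2
a_mellifera	carboxylesterase/esterase		24
a_mellifera	glycosidase		18
a_mellifera	glucuronidase		1
a_mellifera	glycosylase		7
a_mellifera	nitrilase		3
m_rotundata	aldehyde dehydrogenase		18
m_rotundata	catalase		5
m_rotundata	cytochrome P450		52
m_rotundata	cytochrome P450	CYP4	6
m_rotundata	cytochrome P450	CYP6	19
m_rotundata	thioredoxin/glutaredoxin		3
m_rotundata	peroxidase		9
m_rotundata	superoxide dismutase		8
m_rotundata	acyltransferase		8
m_rotundata	glutathione S-transferase		9
m_rotundata	glutathione S-transferase	sigma-GST	1
m_rotundata	glutathione S-transferase	epsilon-GST	0
m_rotundata	sulfotransferase		5
m_rotundata	UDP-glucuronosyltransferase		2
m_rotundata	acid/alkaline phosphatase		2
m_rotundata	amidase		7
m_rotundata	aminopeptidase		27
m_rotundata	amylase		2
m_rotundata	carboxylesterase/esterase		22
m_rotundata	glycosidase		5
m_rotundata	glucuronidase		2
m_rotundata	glycosylase		6
m_rotundata	nitrilase		2
d_melanogaster	aldehyde dehydrogenase		23
d_melanogaster	catalase		3
d_melanogaster	cytochrome P450		85
d_melanogaster	cytochrome P450	CYP4	22
d_melanogaster	cytochrome P450	CYP6	22
d_melanogaster	thioredoxin/glutaredoxin		7
d_melanogaster	peroxidase		20
d_melanogaster	superoxide dismutase		6
d_melanogaster	acyltransferase		55
d_melanogaster	glutathione S-transferase		42
d_melanogaster	glutathione S-transferase	sigma-GST	1
d_melanogaster	glutathione S-transferase	epsilon-GST	10
d_melanogaster	sulfotransferase		15
d_melanogaster	UDP-glucuronosyltransferase		7
d_melanogaster	acid/alkaline phosphatase		16
d_melanogaster	amidase		12
d_melanogaster	aminopeptidase		41
d_melanogaster	amylase		15
d_melanogaster	carboxylesterase/esterase		54
d_melanogaster	glycosidase		29
d_melanogaster	glucuronidase		4
d_melanogaster	glycosylase		5
d_melanogaster	nitrilase		2
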