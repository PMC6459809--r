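source	target	annotation	citation
PFC	AcbC	glutamatergic	Sesack1992
PFC	AcbSh	glutamatergic	Sesack1992
PFC	BLA	glutamatergic	Vertes2004
BLA	AcbC	glutamatergic	Kelley1982
BLA	AcbSh	glutamatergic	Britt2012
BLA	CeA	glutamatergic	Sah2003
BLA	BNST	glutamatergic	Dong2001
CeA	BNST	GABAergic	Sun1993
CeA	VTA	GABAergic	Gonzales2012
BNST	VTA	GABAergic_glutamatergic	Jennings2013
AcbSh	VTA	GABAergic_D1_MSN	Bocklisch2013
VTA	AcbC	dopaminergic	Swanson1982
VTA	AcbSh	dopaminergic	Swanson1982
VTA	PFC	dopaminergic	Swanson1982
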