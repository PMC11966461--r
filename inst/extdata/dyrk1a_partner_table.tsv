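symbol	alias	is_bait	psm_cter	psm_nter	phospho	known_partner	known_sources	disease_printed	disease_class	pli	correlation
DYRK1A		TRUE	97	80	Y321	NA		NDD	NDD	1	1
DCAF7		FALSE	56	38		yes	a,c,d,e,f	NA	none	0.93	0.81
FAM117B		FALSE	21	12	S106	yes	a,c,d,f	NA	none	0.01	0.80
FAM53C		FALSE	13	11	S324	yes	a,c,d,e,f	NA	none	0.07	0.12
PHLDB2		FALSE	8	15		no		NA	none	0	-0.31
GLCCI1		FALSE	16	6	S30,S303	yes	a,b,c,d,e	NA	none	0.06	0.63
FAM117A		FALSE	15	5		yes	a,d	NA	none	0	-0.14
EFHD1		FALSE	5	5		no		NA	none	0.01	-0.64
TRMT61B		FALSE	34	0		yes	b,c	NA	none	0	0.58
FN1		FALSE	31	0		yes	c	Others	other	0	-0.11
FGG		FALSE	8	0		no		Other	other	0	-0.17
PRKAR1A		FALSE	8	0		yes	a,d,f	NDD & Others	NDD	0.09	0.07
TROAP		FALSE	7	1		yes	a,b,c,d	NA	none	0	0.32
CYFIP2		FALSE	6	1		no		NDD (DEE 65)	NDD	1	0.10
LZTS2		FALSE	6	0		yes	a,b,d,f	NA	none	0.05	-0.49
CNOT1		FALSE	5	0		yes	d	NDD	NDD	1	0.81
DHCR7		FALSE	5	0		no		NDD	NDD	0	-0.04
GSPT1		FALSE	5	0		no		NA	none	1	0.85
PSMD7		FALSE	5	0		no		NA	none	0.26	0.28
SLC25A13		FALSE	5	0		no		Other	other	0	0.04
UNC119B		FALSE	5	0		yes	d	Other	other	0.78	0.22
SMC3		FALSE	6	0		no		NDD	NDD	NA	0.70
CDC42BPB		FALSE	3	8		no		NDD	NDD	1	0.07
IGHA1		FALSE	2	7		no		NA	none	NA	-0.34
NEXN		FALSE	3	5		no		Other	other	1	-0.26
RPA1		FALSE	2	6		no		Other	other	0	0.31
RNF114	ZNF313	FALSE	0	19		no		NA	none	0.05	-0.09
CDC27	ANAPC3	FALSE	0	18		yes	c	NA	none	1	0.55
RECQL		FALSE	0	10		no		Other	other	0	0.69
ANAPC7		FALSE	0	8		no		NDD	NDD	0.85	0.35
CDC23	ANAPC8	FALSE	0	7		yes	c	NA	none	0.99	0.46
AGO1		FALSE	0	6		no		NDD	NDD	1	NA
CDC16	ANAPC6	FALSE	0	6		no		NA	none	0.61	0.44
PRRC2B		FALSE	0	6		no		NA	none	1	0.69
ADAR		FALSE	0	5		no		NDD	NDD	0.61	0.59
ANAPC4		FALSE	0	5		yes	c	NA	none	0	1
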