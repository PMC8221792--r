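c13_id	gsmm_id	sign	subsystem
GLYC_13	GLYC	1	Glycolysis
PPP_OX	PPP	1	PPP
PPP_NET	PPP	1	PPP
PPP_NET	PPPNOX	-1	PPP
LDH_NET	LDH	1	Pyr metabolism
PYR_MITO	PYRtm	1	Pyr metabolism
PDH_13	PDH	1	Pyr metabolism
CS_TCA	TCA	1	TCA
AKG_OX	AKGOX	1	TCA
TCA_FULL	TCA	1	TCA
TCA_FULL	AKGOX	1	TCA
GLS_13	GLS	1	AA metabolism
GDH_NET	GDH	1	AA metabolism
ALATA_TOTAL	ALATA	1	AA metabolism
ALATA_TOTAL	ALATA_m	1	AA metabolism
SERD_NET	SERD	1	AA metabolism
GLYS_13	GLYS	1	AA metabolism
GLYCL_13	GLYCL	1	AA metabolism
HISDEG_13	HISDEG	1	AA metabolism
LYSDEG_13	LYSDEG	1	AA metabolism
THRDEG_13	THRDEG	1	AA metabolism
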