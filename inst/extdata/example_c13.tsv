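#dataset_id	example
c13_id	value	ci_low	ci_high	subsystem
GLYC_13	0.1385230471621	0.1385230471621	0.1385230471621	Glycolysis
PPP_OX	0.0146277455021758	0.0146277455021758	0.0146277455021758	PPP
PPP_NET	0.00365693637554397	0.00365693637554397	0.00365693637554397	PPP
LDH_NET	0	0	0	Pyr metabolism
PYR_MITO	0.315937574515254	0.315937574515254	0.315937574515254	Pyr metabolism
PDH_13	0.393247493920027	0.393247493920027	0.393247493920027	Pyr metabolism
CS_TCA	0.393247493920027	0.393247493920027	0.393247493920027	TCA
AKG_OX	0.0773099194047722	0.0773099194047722	0.0773099194047722	TCA
TCA_FULL	0.470557413324799	0.470557413324799	0.470557413324799	TCA
GLS_13	0.0570419916141616	0.0570419916141616	0.0570419916141616	AA metabolism
GDH_NET	0.0891183819235538	0.0891183819235538	0.0891183819235538	AA metabolism
ALATA_TOTAL	-0.0118084625187816	-0.0118084625187816	-0.0118084625187816	AA metabolism
SERD_NET	0.0147872034210427	0.0147872034210427	0.0147872034210427	AA metabolism
GLYS_13	0	0	0	AA metabolism
GLYCL_13	0.0132978329711977	0.0132978329711977	0.0132978329711977	AA metabolism
HISDEG_13	0.0103189861881897	0.0103189861881897	0.0103189861881897	AA metabolism
LYSDEG_13	0.013672367730247	0.013672367730247	0.013672367730247	AA metabolism
THRDEG_13	0.0122958142512298	0.0122958142512298	0.0122958142512298	AA metabolism
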