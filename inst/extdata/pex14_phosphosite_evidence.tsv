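# Phosphopeptide evidence for yeast Pex14p, one row per (peptide, protease
# digest) observation. positions/residues/loc_probs are aligned semicolon
# lists; positions are protein coordinates counting the initiator Met as 1.
# The source table reports per-site localization probabilities only; every
# reported observation satisfied the PEP < 0.01 reporting filter, so the
# pep column carries a nominal synthetic value of 0.001.
window	positions	residues	protease	loc_probs	pep	table_row
MSDVVpSKDRKAL	6	S	aspn	0.998	0.001	1
RKALFDpSAVSFLK	15	S	trypsin	0.999	0.001	2
IVGDEVpSKKIGST	65	S	aspn	1	0.001	3
IVGDEVpSKKIGST	65	S	lysc	1	0.001	3
IVGDEVpSKKIGST	65	S	trypsin	1	0.001	3
STENRApSQDMYLY	76	S	aspn	1	0.001	4
TIDKFVpSDNDGMQ	214	S	lysc	1	0.001	5
TIDKFVpSDNDGMQ	214	S	trypsin	0.972	0.001	5
NRLFSIpSPNGIPG	254	S	aspn	0.999	0.001	6
GIDTIPpSASEILA	266	S	aspn	1	0.001	7
GIDTIPpSASEILA	266	S	trypsin	1	0.001	7
MGMQEEpSDKEKEN	280	S	aspn	1	0.001	8
MGMQEEpSDKEKEN	280	S	trypsin	1	0.001	8
KEKENGpSDANKDD	288	S	lysc	1	0.001	9
KEKENGpSDANKDD	288	S	trypsin	1	0.001	9
KKAREQpTIDSNAS	307	T	aspn	1	0.001	10
KKAREQpTIDSNAS	307	T	trypsin	1	0.001	10
REQTIDpSNASIPE	310	S	aspn	0.972	0.001	11
REQTIDpSNASIPE	310	S	lysc	0.978	0.001	11
REQTIDpSNASIPE	310	S	trypsin	0.999	0.001	11
TIDSNApSIPEWQK	313	S	lysc	1	0.001	12
TIDSNApSIPEWQK	313	S	trypsin	1	0.001	12
TAANEIpSVPDWQN	327	S	trypsin	1	0.001	13
QDNRLFpSIpSPNGIPG	252;254	S;S	aspn	1;1	0.001	14
QDNRLFpSIpSPNGIPG	252;254	S;S	trypsin	1;1	0.001	14
NRLFSIpSPNGIPGIDpTIPSASE	254;263	S;T	trypsin	0.977;1	0.001	15
GIDTIPpSApSEILAKM	266;268	S;S	aspn	0.994;0.996	0.001	16
KKAREQpTIDpSNASIPE	307;310	T;S	trypsin	1;1	0.001	17
KAREQpTIDSNApSIPEWQK	307;313	T;S	lysc	0.999;1	0.001	18
KAREQpTIDSNApSIPEWQK	307;313	T;S	trypsin	1;0.999	0.001	18
AREQTIDpSNApSIPEWQK	310;313	S;S	aspn	1;0.999	0.001	19
AREQTIDpSNApSIPEWQK	310;313	S;S	lysc	1;1	0.001	19
AREQTIDpSNApSIPEWQK	310;313	S;S	trypsin	1;1	0.001	19
KAREQpTIDpSNApSIPEWQK	307;310;313	T;S;S	trypsin	1;1;1	0.001	20
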