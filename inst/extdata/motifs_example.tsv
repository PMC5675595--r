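motif_id	rbp_name	iupac_pattern
SRSF1_1	SRSF1	KGRWGSM
RBFOX1_1	RBFOX1	UGCAUG
PUM1_1	PUM1	UGUANAUA
ELAVL1_1	ELAVL1	UUUUUUU
NOVA1_1	NOVA1	YCAY
KHDRBS1_1	KHDRBS1	AUAAA
PCBP1_1	PCBP1	CCYCC
HNRNPA1_1	HNRNPA1	UAGGGW
QKI_1	QKI	ACUAAY
MBNL1_1	MBNL1	YGCY
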