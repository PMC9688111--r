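partner	role	tbm	arg_position	truncated
AMOT	Hippo/YAP signaling	RQEPQGQE	77	FALSE
Arpin	Cell migration	REQGDGAE	213	FALSE
ATG9A	Pexophagy	RLPGLGEA	233	FALSE
Axin1	Wnt signaling	RPPVPGEE	22	FALSE
CASC3	Pre-mRNA splicing	RQSGDGQE	146	FALSE
Dicer1	RNA interference	RELPDGTF	656	FALSE
GMD	GDP-mannose 4,6 dehydratase	RGSGDGEM	12	FALSE
Golgin-45	Golgi structure and protein maturation	RGAGDGME	18	FALSE
IRAP	Vesicle trafficking	RQSPDGAC	96	FALSE
Mcl-1	Apoptosis regulation	RPPPIGAE	78	FALSE
MERIT40	DNA damage repair	RSNPEGAE	28	FALSE
MERIT40	DNA damage repair	RSEGEGEA	48	FALSE
NKD2	Wnt signaling	RESPEGDS	16	FALSE
Notch2	Notch signaling	RREPVGQD	1726	FALSE
NuMA	Mitotic spindle assembly	RTQPDGTS	1743	FALSE
PEX14	Peroxisome homeostasis	RMEVQGEE	310	FALSE
PEX14	Peroxisome homeostasis	RRGGDGQI	350	FALSE
SH3BP2	Osteoclast formation	RSPPDGQS	415	FALSE
SH3BP5	Epithelial lumen formation	RGCGVGAE	269	FALSE
SH3BP5	Epithelial lumen formation	RSECSGAS	368	FALSE
SOX9	Chondrocyte differentiation	RPLPEGGR	257	FALSE
SOX9	Chondrocyte differentiation	RDVDIGEL	271	FALSE
Striatin	Dendritic Ca2+ signaling	RSAGDGTD	302	FALSE
TAB182	Cytoskeletal maintenance	RPQPDGEA	1508	FALSE
TRF1	Telomere maintenance	RGCADGRD	13	FALSE
USP25	Ubiquitin protease	RTPADGR	1049	TRUE
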