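sample	gene	protein_change	evidence
UIG008	ENTPD1	p.Lys5GlnfsTer11	PVS1_S+PS2_M+PM2_P
UIG008	ENTPD1	p.Asp6AlafsTer2	PVS1_S+PS2_M+PM2_P
UIG12	PROC	p.Gln174Ter	PVS1+PM2_P+PP5
UIG14	SPTBN2	p.Glu652Gly	PS2_M+PM2_P
UIG14	SPTBN2	p.Glu654Gly	PS2_M+PM2_P
UIG031	L1CAM	p.Asp1158Gly	PM2_P+PP3
UIG038	DYNC1H1	p.Ile4486Thr	PS2_M+PM2_P
UIG038	NTRK1	p.Ala155Thr	PM2_P+PP3
UIG038	NTRK1	p.Gly582Asp	PM2_P+PP3
UIG044	TUBA1A	p.Ser287Thr	PS2_M+PM2_P
UIG067	PDK3	p.Glu17Gly	PS2_M+PM2_P
UIG144	TH	p.Ala317Glu	PM2_P+PP3
UIG144	TH	p.Gln150Pro	PM2_P
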