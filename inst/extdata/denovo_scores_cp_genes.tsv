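case	gene	protein_change	inheritance	sift_score	polyphen_score	cadd_phred
UIG009	PROC	p.Glu127Gly	AD	0	0.713	21
UIG14	SPTBN2	p.Glu654Gly	AD	0.01	0.852	26
UIG14	SPTBN2	p.Glu652Gly	AR	0	0.999	26.9
UIG011	WDR81	p.Ala1340Val	AR	0	0.987	25.8
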