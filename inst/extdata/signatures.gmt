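cytolytic_index	geometric_mean of GZMA and PRF1 (intratumoral cytolytic activity)	GZMA	PRF1
ifng_signature	mean_log 6-gene interferon-gamma signature	IDO1	CXCL10	CXCL9	HLA-DRA	STAT1	IFNG
expanded_immune_signature	mean_log 18-gene expanded immune signature	CD3D	IDO1	CIITA	CD3E	CCL5	GZMK	CD2	HLA-DRA	CXCL13	IL2RG	NKG7	HLA-E	CXCR6	LAG3	TAGAP	CXCL10	STAT1	GZMB
cd8_exhaustion_signature	mean_log CD8 T-cell exhaustion signature	LAG3	HAVCR2	PDCD1	CTLA4	TIGIT	ENTPD1	BATF	EOMES	TOX	CD244	CD160	TBX21
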