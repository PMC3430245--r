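# Published net between-clade distances (European vs Asian swine mtDNA),
# in percent, one row per dated partition.
region	K_percent	K_sd
cytb_synonymous	3.875	0.011
cytb_nonsynonymous	0.154	0.001
dloop_ETAS	2.273	0.006
dloop_central	0.843	0.004
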