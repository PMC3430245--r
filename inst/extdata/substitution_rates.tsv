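# Published mammalian mtDNA substitution rates per region,
# in units of 1e-9 substitutions/site/year (value +/- SD).
region	rate_1e9	rate_sd
cytb_synonymous	27.4	3.3
cytb_nonsynonymous	1.8	0.3
dloop_ETAS	19.4	7.8
dloop_central	3.8	1.9
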