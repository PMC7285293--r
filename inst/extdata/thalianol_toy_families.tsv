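gene_id	family
THAH	P450
THAS	TPS
THAD	P450
CYP705A12	P450
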