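composition_id	drug_id
comp_a	xypq
comp_b	xypq
comp_c	xypq
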