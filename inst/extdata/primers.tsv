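label	sequence	role
PCR1	GGGTATTGGACATCCATCCT	forward
PCR2	GTCCAGTTTTCTTGGCATTG	forward
PCR3	TAGAAAGCTTCTAATGTGGGTG	forward
common_rev	GGATTCCTCTCCCTTGGAAT	reverse
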