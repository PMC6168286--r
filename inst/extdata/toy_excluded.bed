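c2	15000	17000	tel_amplified	0	.
c1	20000	22000	ty_amplified	0	.
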