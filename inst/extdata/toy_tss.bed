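c2	940	941	gA	83	+
c2	960	961	gA	17	+
c2	6070	6071	gB	55	-
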