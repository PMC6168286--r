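c1	30000
c2	20000
cM	5000
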