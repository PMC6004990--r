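class	subtype1	subtype2	subtype3	control
subtype1	141	16	11	14
subtype2	37	157	16	8
subtype3	26	43	56	11
control	1	3	5	72
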