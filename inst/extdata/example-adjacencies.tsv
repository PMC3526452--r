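# figure-eight example: two cycles sharing the duplicated marker v
v	a	1
a	b	1
b	v	1
v	c	1
c	d	1
d	v	1
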