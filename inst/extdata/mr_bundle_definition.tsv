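# Curated 170-residue microbial rhodopsin 7TM bundle definition.
# anchor_conservation: percent conservation of the h.50 anchor across the
# family alignment (metadata only).
helix	common_start	common_end	anchor_label	anchor_conservation
A	1.34	1.55	1.50	64
B	2.33	2.56	2.50	95
C	3.46	3.67	3.50	98
D	4.33	4.56	4.50	95
E	5.30	5.57	5.50	70
F	6.36	6.60	6.50	98
G	7.36	7.60	7.50	100
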