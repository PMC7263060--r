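subtype	class	strong_a	weak_a	weak_b	strong_b
AD	nonNE	9	4	0	1
SQC	nonNE	10	2	1	0
AT	NE	0	0	8	0
TC	NE	0	3	15	5
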