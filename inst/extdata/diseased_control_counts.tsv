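diagnosis	n	false_positives
FSGS	31	2
IgAN	70	9
MN	46	2
MCD	29	2
DNP	83	8
AKI	16	0
Fanconi	11	0
Renal diseases, others	10	0
DM type 1 without DNP	42	7
DM type 2 without DNP	12	0
SLE	45	6
Vasculitis	12	1
Bladder cancer	22	1
Liver transplantation	6	0
Stem cell transplantation	46	9
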