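cohort	group	n	positive
CRISP ADPKD	case	224	189
SUISSE ADPKD holdout	case	27	23
Healthy controls	control	86	5
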