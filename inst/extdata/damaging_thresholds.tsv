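predictor	cutoff	direction
ssep	-0.301	below
SIFT	0.05	below
SIFT4G	0.05	below
Polyphen2_HDIV	0.453	above
Polyphen2_HVAR	0.447	above
LRT	0.001	below
MutationTaster	0.5	above
PROVEAN	-2.5	below
FATHMM	-1.5	below
MetaSVM	0	above
MetaLR	0.5	above
MetaRNN	0.5	above
REVEL	0.5	above
CADD	20	above
DEOGEN2	0.5	above
BayesDel_addAF	0.0692	above
BayesDel_noAF	-0.057	above
ClinPred	0.5	above
AlphaMissense	0.564	above
ESM1b	-7.5	below
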