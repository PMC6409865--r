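gene	degree	aspl	cc	bc
TP53	178	2.57	0.39	0.117
TNF	137	2.12	0.47	0.0164
EGFR	228	2.38	0.42	0.0306
VEGFA	85	2.23	0.45	0.00805
APOE	68	2.50	0.40	0.0103
IL6	100	2.18	0.46	0.0145
TGFB1	96	2.46	0.41	0.0359
MTHFR	102	2.45	0.41	0.0663
ESR1	122	2.55	0.39	0.0641
AKT1	141	1.99	0.50	0.123
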