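construct	transition	tm_c	se_c	model
EPHA2_heteroduplex	single	53.48	0.32	monophasic
EPHA2_duplex	single	70.74	0.22	monophasic
EPHA2_triplex	first	49.52	0.22	biphasic
EPHA2_triplex	second	70.00	NA	biphasic
EPHA2_CTGA_hairpin	single	80.41	0.10	monophasic
EPHA2_CTGA_triplex	first	50.08	0.51	biphasic
EPHA2_CTGA_triplex	second	79.90	0.10	biphasic
ADM_duplex	single	63.80	0.20	monophasic
ADM_CTGA_hairpin	single	95.76	16.69	monophasic
ADM_CTGA_triplex	first	40.24	2.62	biphasic
ADM_CTGA_triplex	second	81.78	0.59	biphasic
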