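sample	SOC	pH	AP	TP	NO3	NH4	sand	silt	clay
GH	0.61	0.17	0.01	1.64	0.43	0.06	7.97	67.21	75.07
HB	1.55	0.02	0.03	0.59	0.19	0.14	12.39	44.12	54.37
KC	3.11	0.03	0.03	0.80	0.21	0.13	5.43	63.30	65.75
ZS	0.15	0.07	0.02	1.28	0.51	0.22	4.23	75.00	74.75
YX	0.68	0.05	0.01	1.56	0.19	0.30	7.78	51.93	48.84
ZT	0.72	0.11	0.02	0.61	0.13	0.04	7.35	37.08	44.39
ZW	0.20	0.02	0.02	0.99	0.06	0.21	9.08	17.76	36.11
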