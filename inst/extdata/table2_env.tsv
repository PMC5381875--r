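sample	SOC	pH	AP	TP	NO3	NH4	sand	silt	clay
GH	26.37	3.84	0.41	36.01	9.43	3.93	56.56	554.78	388.66
HB	25.42	4.19	0.35	26.48	9.32	4.20	50.69	527.48	421.83
KC	28.72	4.59	0.34	23.40	8.88	5.26	64.52	526.20	409.28
ZS	29.79	5.25	0.33	23.10	7.06	6.33	52.51	565.69	381.80
YX	9.53	6.96	0.23	23.61	3.42	7.37	63.89	545.07	391.04
ZT	25.74	7.67	0.18	12.98	3.19	10.54	46.92	550.93	402.15
ZW	31.06	7.79	0.16	14.87	0.76	10.77	54.19	519.80	426.01
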