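sample	effective_sequences	otus	coverage	chao1	shannon
ZT	23340	2597.60	87.71	5993.66	6.88
YX	7310	2486.00	79.11	5660.66	6.83
ZW	16648	2434.56	85.49	5837.12	6.69
ZS	16789	2022.24	88.05	4907.14	6.25
KC	24687	1762.64	90.64	4641.77	5.65
HB	14532	1616.80	90.26	3715.13	5.59
GH	17913	1434.48	91.13	3669.13	5.29
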