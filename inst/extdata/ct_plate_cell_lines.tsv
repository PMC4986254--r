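gene_id	MCF-7	MDA-MB-231	MDA-MB-468	T47D	MCF10A
GAPDH	18.51	16.45	20.48	15.66	18.29
B2M	23.97	20.80	25.49	22.14	23.32
ACTB	16.24	13.84	18.09	14.62	17.56
TUBA1A	21.92	20.22	24.94	20.32	22.69
18S	20.49	19.61	23.47	19.56	17.86
CCSER2	29.72	27.47	30.96	28.01	29.96
UBXN4	26.61	24.83	30.49	25.33	28.61
SYMPK	29.46	27.35	30.84	27.34	29.74
TMEM11	27.04	24.69	29.44	24.94	27.98
ANKRD17	28.82	27.12	31.57	26.80	29.25
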