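gene_id	panel	mean	cv_percent
UBXN4	nhkg	81.75	11.45
DHX9	nhkg	158.25	12.42
TMEM11	nhkg	68.12	12.83
LARP1	nhkg	137.87	13.10
STX5	nhkg	65.37	13.33
ANKRD17	nhkg	33.62	14.03
SYMPK	nhkg	60.75	14.29
TAF2	nhkg	23.87	14.41
CCSER2	nhkg	20.00	15.12
MZT2B	nhkg	179.62	15.69
PUM1	thkg	45.50	24.56
RPL13A	thkg	3028.62	25.51
PGK1	thkg	488.37	30.91
GUSB	thkg	70.00	36.56
ACTB	thkg	9500.25	37.06
DIMT1	thkg	26.62	41.82
TUBA1A	thkg	658.00	47.50
GAPDH	thkg	3580.12	66.79
B2M	thkg	1530.12	93.47
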