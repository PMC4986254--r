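gene_id	MCF-7	MDA-MB-231	MDA-MB-468	T47D	MCF10A
CCSER2	29.72351	27.4733	30.9613	28.0175	29.96375
UBXN4	26.61776	24.83932	30.49971	25.33814	28.61279
SYMPK	29.46543	27.3512	30.84297	27.34727	29.74568
TMEM11	27.04637	24.69488	29.44699	24.94886	27.98631
ANKRD17	28.82998	27.12572	31.57093	26.80775	29.25333
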