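# Gene-symbol expansions for the breast-cancer transcription-factor panel.
# Entries that are complexes or families map to their member gene symbols;
# the literal entry name itself always matches as well.
AP1: [JUN, JUNB, JUND, FOS, FOSB]
NFKB: [NFKB1, NFKB2, RELA, RELB, REL]
GATA3: [GATA3]
FOXA1: [FOXA1]
ER: [ESR1]
Elk1: [ELK1]
STAT3: [STAT3]
STAT5: [STAT5A, STAT5B]
HIF: [HIF1A, EPAS1]
NOTCH: [NOTCH1, NOTCH2, NOTCH3, NOTCH4]
SP1: [SP1]
TP53: [TP53]
MYC: [MYC]
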