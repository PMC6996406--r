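# iTRAQ 4-plex isotope impurity percentages (-2/-1/+1/+2 Da satellites).
# PLACEHOLDER values representative of typical 4-plex reagent lots;
# replace with the percentages printed on the vendor certificate of
# analysis for the lot actually used.
tag	minus2	minus1	plus1	plus2
114	0.0	1.0	5.9	0.2
115	0.0	2.0	5.6	0.1
116	0.0	3.0	4.5	0.1
117	0.1	4.0	3.5	0.1
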