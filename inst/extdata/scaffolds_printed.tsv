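# name	length	linkage_group
ChrLG-1	277973	LG1
ChrLG-12	259465	LG12
ChrLG-14	281922	LG14
ChrLG-17	1136344	LG17
ChrLG-21	892712	LG21
ChrLG-22	1327112	LG22
ChrLG-24	488675	LG24
ChrLG-26	78538	LG26
ChrLG-5	328790	LG5
ChrLG-6	496427	LG6
ChrLG-7	172473	LG7
ChrLG-UN	2307228	LGUN
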