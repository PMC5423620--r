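# transcript_id	name	fc	category
Px001339	Larval cuticle protein LCP-30	63.3	Development
Px016045	Larval cuticle protein LCP-30	63.3	Development
Px012314	Death-associated small cytoplasmic leucine-rich protein	40.4	Development
Px010057	Urbain	29.6	Signaling
Px017386	Retinol dehydrogenase	25.4	Metabolism
Px013919	Collagen alpha chain	21.8	Development
Px000870	Hypothetical	16.6	Unknown
Px001530	Neurofilament heavy polypeptide	15.8	Signaling
Px010443	Hypothetical	15.8	Unknown
Px000114	Sulfotransferase	15.1	Metabolism
Px002962	Methyltransferase-like protein	13.4	Development
Px015205	Hypothetical	12.0	Unknown
Px014022	Putative uncharacterized protein	7.6	Unknown
Px009883	Hypothetical	7.5	Unknown
Px003977	Protein lethal essential for life	7.5	Development
Px012012	Hypothetical	7.1	Unknown
Px011355	Hypothetical	6.9	Unknown
Px017694	Hypothetical	6.5	Unknown
Px008075	Protein PF14_0175	5.4	Signaling
Px005453	Putative cuticle protein	5.3	Development
Px017104	Neurofilament heavy polypeptide	5.2	Signaling
Px003919	Hypothetical	5.0	Unknown
Px004656	Alpha-tocopherol transfer protein-like	4.8	Development
Px006831	Hypothetical	4.7	Unknown
Px013516	LIX1-like protein	4.4	Development
Px008280	Hypothetical	4.4	Unknown
Px003203	Hypothetical	4.3	Unknown
Px015340	Hypothetical	4.2	Unknown
Px004490	Adenosine deaminase	4.1	Metabolism
Px008611	Gustatory receptor candidate	3.9	Signaling
Px008150	Scavenger receptor class B member 1	3.8	Signaling
Px012769	Protein lethal essential for life	3.8	Development
Px006105	Glutathione S-transferase	3.7	Metabolism
Px002808	Unknown function	3.6	Unknown
Px014258	Putative cuticle protein	3.4	Development
Px015089	Serpin	3.4	Immune
Px010540	Hypothetical	3.4	Unknown
Px013167	Hypothetical	3.4	Unknown
Px012902	Putative inorganic phosphate cotransporter	3.4	Metabolism
Px001085	Fibrohexamerin	3.4	Metabolism
Px016965	Putative inorganic phosphate cotransporter	3.3	Metabolism
Px012642	Angiotensin-converting enzyme	3.3	Metabolism
Px010625	Hypothetical	3.3	Unknown
Px016161	Neurofilament heavy polypeptide	3.1	Signaling
Px012514	Clavesin-1	3.1	Development
Px008793	Hypothetical	3.1	Unknown
Px002698	Hypothetical	3.0	Unknown
Px008402	Decaprenyl-diphosphate synthase	3.0	Metabolism
Px009195	Ejaculatory bulb-specific protein	3.0	Development
Px010922	Osiris	2.9	Development
Px007085	Putative uncharacterized protein	2.9	Unknown
Px017926	Neprilysin	2.9	Gene expression
Px008400	Probable nuclear hormone receptor	2.9	Signaling
Px004742	Hypothetical	2.7	Unknown
Px009680	Putative uncharacterized protein	2.7	Unknown
Px001678	Hypothetical	2.7	Unknown
Px010913	Proteasome subunit alpha type-2	2.7	Development
Px001472	Hypothetical	2.7	Unknown
Px012390	Hypothetical	2.7	Unknown
Px005488	Helix-loop-helix protein Delilah	2.6	Development
Px015917	Putative cuticle protein CPH36	2.5	Development
Px004516	Clavesin-1	2.5	Development
Px003928	Hypothetical	2.5	Unknown
Px012743	Probable dolichol-phosphate mannosyltransferase	2.4	Metabolism
Px006833	Hypothetical	2.4	Unknown
Px008161	Hypothetical	2.4	Unknown
Px007157	Hypothetical	2.4	Unknown
Px006388	Hypothetical	2.3	Unknown
Px008548	Hypothetical	2.3	Unknown
Px014885	Putative odorant-binding protein A10	2.3	Signaling
Px012010	Hypothetical	2.2	Unknown
Px013082	Putative inorganic phosphate cotransporter	2.2	Metabolism
Px001573	Alpha-tocopherol transfer protein-like	2.2	Development
Px005373	Carboxypeptidase B	2.2	Development
Px010142	Hypothetical	2.2	Unknown
Px008062	Endochitinase	2.2	Development
Px003497	Hypothetical	2.2	Unknown
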