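# target_id	scaffold	start	end	signed_distance	nearest_gene	gene_name	fc	category
vH4-ChIP-1	ChrLG-1	267416	267973	-557	Px013825	Hypothetical	5.0	Unknown
vH4-ChIP-2	ChrLG-5	276105	276260	155	Px008241	Hypothetical	4.2	Unknown
vH4-ChIP-3	ChrLG-5	215111	219713	-602	Px008237	Cleft lip and palate transmembrane protein 1-like protein	-10.3	Signaling
vH4-ChIP-4	ChrLG-5	316488	318790	-473	Px004309	Centrosomal protein of 97 kDa	-3.0	Development
vH4-ChIP-5	ChrLG-6	478831	486427	596	Px003642	Uncharacterized protein KIAA0090 homolog	10.8	Unknown
vH4-ChIP-6	ChrLG-7	156448	162473	-447	Px011497	Zinc finger protein	12.2	Signaling
vH4-ChIP-7	ChrLG-12	239288	249465	472	Px008056	Mitochondrial glutamate carrier	-14.2	Metabolism
vH4-ChIP-8	ChrLG-12	59259	80699	683	Px008047	GJ16239	8.5	Metabolism
vH4-ChIP-9	ChrLG-14	271091	271922	831	Px010174	Putative uncharacterized protein	-10.1	Unknown
vH4-ChIP-10	ChrLG-17	1121617	1126344	-526	Px009354	Protein penguin	8.0	Development
vH4-ChIP-11	ChrLG-21	882018	882712	694	Px002719	HIG1 domain family member 2A	-4.2	Gene expression
vH4-ChIP-12	ChrLG-22	883663	922749	469	Px002998	Polycomb protein eed-A	18.2	Development
vH4-ChIP-13	ChrLG-22	1306408	1317112	-704	Px003709	Uncharacterized protein KIAA1370	-2.3	Unknown
vH4-ChIP-14	ChrLG-24	470439	478675	236	Px006727	Endothelial zinc finger protein induced by TNF alpha	5.0	Development
vH4-ChIP-15	ChrLG-26	50771	68538	767	Px010512	Zinc finger protein	25.1	Signaling
vH4-ChIP-16	ChrLG-UN	16658	37064	406	Px016400	Leucine-rich repeat-containing protein	-7.5	Metabolism
vH4-ChIP-17	ChrLG-UN	107271	120081	810	Px013663	Aldehyde dehydrogenase family 1 member L1	-45.6	Metabolism
vH4-ChIP-18	ChrLG-UN	204710	223658	684	Px017204	SID1 transmembrane family member 1	-40.4	Signaling
vH4-ChIP-19	ChrLG-UN	75155	82548	-582	Px014828	GTPase-activating protein	-25.0	Metabolism
vH4-ChIP-20	ChrLG-UN	12872	14358	829	Px001552	Vacuolar protein sorting-associated protein	24.0	Metabolism
vH4-ChIP-21	ChrLG-UN	224911	226167	-738	Px005358	α-(1,3)-fucosyltransferase	18.2	Metabolism
vH4-ChIP-22	ChrLG-UN	3739	5950	621	Px002154	Mitochondrial intermediate peptidase	18.2	Metabolism
vH4-ChIP-23	ChrLG-UN	1709593	1710105	512	Px005915	Hypothetical	-16.9	Unknown
vH4-ChIP-24	ChrLG-UN	696255	714576	944	Px006800	Dual serine/threonine and tyrosine protein kinase	-16.0	Immune
vH4-ChIP-25	ChrLG-UN	44835	47452	-654	Px005285	Hypothetical	-16	Unknown
vH4-ChIP-26	ChrLG-UN	4769	6486	26	Px017967	Putative transposase ykgN	-14.2	Gene expression
vH4-ChIP-27	ChrLG-UN	88684	107215	828	Px013605	Hypothetical	14.2	Unknown
vH4-ChIP-28	ChrLG-UN	172060	172677	-617	Px005697	Hypothetical	-13.7	Unknown
vH4-ChIP-29	ChrLG-UN	998583	1039637	125	Px014314	Nucleolar MIF4G domain-containing protein 1 homolog	-13.4	Gene expression
vH4-ChIP-30	ChrLG-UN	78554	80038	-832	Px014423	MORN repeat-containing protein	13.1	Gene expression
vH4-ChIP-31	ChrLG-UN	186099	186577	478	Px012337	Hypothetical	13.0	Unknown
vH4-ChIP-32	ChrLG-UN	475306	475995	-689	Px004214	A7S037_NEMVE; Predicted protein	-12.3	Gene expression
vH4-ChIP-33	ChrLG-UN	13224	59610	386	Px015368	Rapamycin-insensitive companion of m-Tor	12.1	Signaling
vH4-ChIP-34	ChrLG-UN	112006	130292	286	Px013363	Exostosin-2	12.0	Gene expression
vH4-ChIP-35	ChrLG-UN	16056	17294	755	Px016880	Facilitated trehalose transporter	-10.4	Development
vH4-ChIP-36	ChrLG-UN	1622315	1627191	876	Px016347	Regulator of G-protein signaling	-10.3	Signaling
vH4-ChIP-37	ChrLG-UN	1345193	1351114	-921	Px006237	Ras-related protein RabJ	-10.1	Signaling
vH4-ChIP-38	ChrLG-UN	600031	600513	-482	Px008214	Probable serine hydrolase	8.6	Metabolism
vH4-ChIP-39	ChrLG-UN	89183	118306	-987	Px010075	Protein PAT1 homolog	-8.4	Gene expression
vH4-ChIP-40	ChrLG-UN	273969	274525	556	Px007509	Hypothetical	7.45	Unknown
vH4-ChIP-41	ChrLG-UN	108141	109100	959	Px009739	Hypothetical	-6.8	Unknown
vH4-ChIP-42	ChrLG-UN	2292630	2293702	-261	Px003250	Larval cuticle protein LCP-30	-6.6	Development
vH4-ChIP-43	ChrLG-UN	2294845	2297228	118	Px003251	Putative cuticle protein	-6.6	Development
vH4-ChIP-44	ChrLG-UN	448023	448313	290	Px004665	Hypothetical	6.5	Unknown
vH4-ChIP-45	ChrLG-UN	709982	756563	122	Px002457	Protein dpy-19 homolog	6.4	Metabolism
vH4-ChIP-46	ChrLG-UN	1513940	1538960	543	Px006242	UBX domain-containing protein 4	5.8	Gene expression
vH4-ChIP-47	ChrLG-UN	192843	194073	-891	Px012789	Hypothetical	-10.7	Unknown
vH4-ChIP-48	ChrLG-UN	390910	391918	312	Px003836	Hypothetical	-7.7	Unknown
vH4-ChIP-49	ChrLG-UN	417484	423132	648	Px004564	Hypothetical	-6.5	Unknown
vH4-ChIP-50	ChrLG-UN	288781	289959	669	Px005650	Probable 39S ribosomal protein L45	6.3	Gene expression
vH4-ChIP-51	ChrLG-UN	1681979	1682541	-562	Px002590	Trypsin	-4.9	Development
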