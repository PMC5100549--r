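species	accession	length	subfamily	sub_subfamily	is_fragment
Dendroaspis polylepis	P25687	81	AVIT (prokineticin)		FALSE
Dendroaspis angusticeps	P28374	38	Natriuretic peptide		FALSE
Dendroaspis angusticeps	Q8QGP7	53	Natriuretic peptide		FALSE
Naja melanoleuca	P01383	71	Long-chain 3FTx	T2-alpha-NT	FALSE
Naja melanoleuca	P01388	71	Long-chain 3FTx	T2-alpha-NT	FALSE
Naja nivea	P01390	71	Long-chain 3FTx	T2-alpha-NT	FALSE
Naja haje	P25674	71	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis jamesoni	P01393	72	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis viridis	P01394	72	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis viridis	P01395	73	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis polylepis	P01396	72	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis polylepis	P01397	72	Long-chain 3FTx	T2-alpha-NT	FALSE
Dendroaspis polylepis	P25667	72	Long-chain 3FTx	T2-alpha-NT	FALSE
Naja melanoleuca	P01400	65	Non-conventional 3FTx	ORP-II	FALSE
Naja haje	P01401	65	Non-conventional 3FTx	ORP-II	FALSE
Naja nivea	P25680	65	Non-conventional 3FTx	ORP-II	FALSE
Dendroaspis jamesoni	P25682	63	Non-conventional 3FTx	ORP-XIX	FALSE
Dendroaspis angusticeps	C0HJB0	57	Short-chain 3FTx		FALSE
Dendroaspis polylepis	P0DKR6	78	Short-chain 3FTx		FALSE
Dendroaspis polylepis	P0DKS3	57	Short-chain 3FTx		FALSE
Dendroaspis angusticeps	P0C1Y9	61	Short-chain 3FTx	FAS	FALSE
Dendroaspis angusticeps	P0C1Z0	61	Short-chain 3FTx	FAS	FALSE
Dendroaspis polylepis	P25681	61	Short-chain 3FTx	FAS	FALSE
Dendroaspis angusticeps	Q9PS08	30	Short-chain 3FTx	FAS	TRUE
Dendroaspis jamesoni	P01407	62	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P01408	63	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P01409	63	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P01410	62	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P01411	62	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P17696	86	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P18328	86	Short-chain 3FTx	AMI	FALSE
Dendroaspis polylepis	P25518	65	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P60234	65	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P60235	40	Short-chain 3FTx	AMI	TRUE
Dendroaspis angusticeps	P60236	40	Short-chain 3FTx	AMI	TRUE
Dendroaspis polylepis	P80494	66	Short-chain 3FTx	AMI	FALSE
Dendroaspis polylepis	P80495	65	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P81030	66	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P81031	65	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P85092	65	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	P86419	66	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	Q8QGR0	86	Short-chain 3FTx	AMI	FALSE
Dendroaspis angusticeps	Q9PSN1	66	Short-chain 3FTx	AMI	FALSE
Dendroaspis jamesoni	P01413	61	Short-chain 3FTx	ANP	FALSE
Dendroaspis jamesoni	P28375	59	Short-chain 3FTx	ANP	FALSE
Dendroaspis angusticeps	P81946	59	Short-chain 3FTx	ANP	FALSE
Dendroaspis polylepis	P01414	60	Short-chain 3FTx	LTC	FALSE
Dendroaspis polylepis	P22947	60	Short-chain 3FTx	LTC	FALSE
Dendroaspis jamesoni	P25683	60	Short-chain 3FTx	LTC	FALSE
Dendroaspis angusticeps	P25684	60	Short-chain 3FTx	LTC	FALSE
Naja haje	P01415	61	Short-chain 3FTx	ORP-VI	FALSE
Dendroaspis angusticeps	P18329	80	Short-chain 3FTx	ORP-XI	FALSE
Dendroaspis angusticeps	P01404	81	Short-chain 3FTx	ORP-XI	FALSE
Dendroaspis viridis	P01405	60	Short-chain 3FTx	ORP-XI	FALSE
Dendroaspis jamesoni	P01406	60	Short-chain 3FTx	ORP-XI	FALSE
Dendroaspis angusticeps	Q9PS09	30	Short-chain 3FTx	ORP-XI	TRUE
Naja melanoleuca	P01473	61	Short-chain 3FTx	ORP-XV	FALSE
Naja melanoleuca	P01474	61	Short-chain 3FTx	ORP-XV	FALSE
Naja haje	P62394	62	Short-chain 3FTx	ORP-XV	FALSE
Dendroaspis angusticeps	P60237	63	Short-chain 3FTx	TB-MUS	FALSE
Naja nivea	P01423	61	Short-chain 3FTx	T1-alpha-NT	FALSE
Naja melanoleuca	P01424	61	Short-chain 3FTx	T1-alpha-NT	FALSE
Naja haje	P25675	61	Short-chain 3FTx	T1-alpha-NT	FALSE
Naja haje	P68418	61	Short-chain 3FTx	T1-alpha-NT	FALSE
Naja nivea	P68419	61	Short-chain 3FTx	T1-alpha-NT	FALSE
Dendroaspis polylepis	P01416	60	Short-chain 3FTx	T1-alpha-NT	FALSE
Dendroaspis jamesoni	P01417	60	Short-chain 3FTx	T1-alpha-NT	FALSE
Dendroaspis viridis	P01418	60	Short-chain 3FTx	T1-alpha-NT	FALSE
Dendroaspis jamesoni	P01419	58	Short-chain 3FTx	T1-alpha-NT	FALSE
Naja melanoleuca	P01448	60	Short-chain 3FTx	T1A-CYT	FALSE
Naja nivea	P01456	60	Short-chain 3FTx	T1A-CYT	FALSE
Naja haje	P01457	60	Short-chain 3FTx	T1A-CYT	FALSE
Naja nivea	P01458	60	Short-chain 3FTx	T1A-CYT	FALSE
Naja nivea	P01463	60	Short-chain 3FTx	T1A-CYT	FALSE
Dendroaspis polylepis	P00979	60	Kunitz-type		FALSE
Dendroaspis angusticeps	P00980	59	Kunitz-type		FALSE
Dendroaspis polylepis	P00981	79	Kunitz-type		FALSE
Dendroaspis angusticeps	P00982	57	Kunitz-type		FALSE
Dendroaspis polylepis	P00983	57	Kunitz-type		FALSE
Dendroaspis polylepis	P00984	59	Kunitz-type		FALSE
Dendroaspis angusticeps	P0DMJ6	59	Kunitz-type		FALSE
Dendroaspis angusticeps	P81658	60	Kunitz-type		FALSE
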