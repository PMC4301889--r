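snp_id	chrom	pos	ref	alt
snp01	chr16	72802000	T	G
snp02	chr16	72806766	G	T
snp03	chr16	72811532	G	C
snp04	chr16	72816298	G	A
snp05	chr16	72821064	G	T
snp06	chr16	72825830	G	C
snp07	chr16	72830596	C	T
snp08	chr16	72835362	T	A
snp09	chr16	72840128	C	T
snp10	chr16	72844894	G	T
snp11	chr16	72849660	G	A
snp12	chr16	72854426	G	A
snp13	chr16	72859192	T	G
snp14	chr16	72863958	C	G
snp15	chr16	72868724	A	G
snp16	chr16	72873490	T	C
snp17	chr16	72878256	C	G
snp18	chr16	72883022	G	T
snp19	chr16	72887788	C	G
rs740178	chr16	72892554	G	T
snp21	chr16	72897320	T	C
rs8060701	chr16	72902086	A	C
snp23	chr16	72906852	A	C
snp24	chr16	72911618	G	A
snp25	chr16	72916384	T	G
snp26	chr16	72921150	G	C
snp27	chr16	72925916	A	G
snp28	chr16	72930682	G	A
snp29	chr16	72935448	C	A
snp30	chr16	72940214	A	T
snp31	chr16	72944980	C	G
snp32	chr16	72949746	A	C
snp33	chr16	72954512	T	A
snp34	chr16	72959278	C	A
snp35	chr16	72964044	C	T
snp36	chr16	72968810	A	T
snp37	chr16	72973576	C	T
snp38	chr16	72978342	C	G
snp39	chr16	72983108	G	C
rs10852515	chr16	72986608	A	C
snp41	chr16	72990108	G	C
snp42	chr16	72994874	T	A
snp43	chr16	72999640	A	C
snp44	chr16	73004406	T	A
snp45	chr16	73009172	C	T
snp46	chr16	73013938	C	G
snp47	chr16	73018704	G	A
snp48	chr16	73023470	A	C
snp49	chr16	73028236	A	C
snp50	chr16	73033002	C	A
snp51	chr16	73037768	C	G
snp52	chr16	73042534	G	C
snp53	chr16	73047300	T	A
snp54	chr16	73052066	A	C
snp55	chr16	73056832	C	T
snp56	chr16	73061598	T	G
snp57	chr16	73066364	C	T
snp58	chr16	73071130	G	T
snp59	chr16	73075896	C	A
snp60	chr16	73080662	G	T
snp61	chr16	73085428	A	C
snp62	chr16	73090194	T	C
snp63	chr16	73094960	C	T
snp64	chr16	73099726	A	T
snp65	chr16	73104492	G	A
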