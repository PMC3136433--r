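# Known cell-penetrating peptides compiled from the literature and vendors (n=111)
cpp001	AAVALLPAVLLALLAKNNLKDCGLF
cpp002	AAVALLPAVLLALLAKNNLKECGLY
cpp003	AAVALLPAVLLALLAPVQRKQKLMP
cpp004	AAVALLPAVLLALLAVTDQLGEDFFAVDLEAFLQEFGLLPEKE
cpp005	AAVLLPVLLAAP
cpp006	AGYLLGKINLKALAALAKKIL
cpp007	AGYLLGKLKALAALAKKIL
cpp008	AHALCLTERQIKIWFQNRRMKWKKEN
cpp009	AHALCPPERQIKIWFQNRRMKWKKEN
cpp010	ALWKTLLKKVLKA
cpp011	AYALCLTERQIKIWFANRRMKWKKEN
cpp012	CGPGSDDEAAADAQHAAPPKKKRKVGY
cpp013	CNGRC
cpp014	CNGRCG
cpp015	CNGRCGGKKLKLLKLL
cpp016	CNGRCGGKLAKLAKLAKLAK
cpp017	CNGRCGGLVTT
cpp018	GAARVTSWLGRQLRIAGKRLEGRSK
cpp019	GALFLGFLGAAGSTMGAWSQPKSKRKV
cpp020	GGRQIKIWFQNRRMKWKK
cpp021	GIGKFLHSAKKWGKAFVGQIMNC
cpp022	GLAFLGFLGAAGSTMGAWSQPKSKRKV
cpp023	GRKKRRQ
cpp024	GRKKRRQRRPPQC
cpp025	GRKKRRQRRRC
cpp026	GRKKRRQRRRPPC
cpp027	GRKKRRQRRRPQ
cpp028	GRQLRIAGKRLEGRSK
cpp029	GWTLNPAGYLLGKINLKALAALAKKIL
cpp030	GWTLNPPGYLLGKINLKALAALAKKIL
cpp031	GWTLNSAGYLLGKINLKALAALAKKIL
cpp032	GWTLNSAGYLLGKINLKALAALAKKLL
cpp033	GWTLNSAGYLLGKLKALAALAKKIL
cpp034	GWTLNSKINLKALAALAKKIL
cpp035	INLKALAALAKKIL
cpp036	IWFQNRRMKWKK
cpp037	KALAALLKKWAKLLAALK
cpp038	KALAKALAKLWKALAKAA
cpp039	KALKKLLAKWAAAKALL
cpp040	KCRKKKRRQRRRKKLSECLKRIGDELDS
cpp041	KCRKKKRRQRRRKKPVVHLTLRQAGDDFSR
cpp042	KETWWETWWTEWSQPKKKRKV
cpp043	KETWWETWWTEWSQPKKRKV
cpp044	KFHTFPQTAIGVGAP
cpp045	KITLKLAIKAWKLALKAA
cpp046	KIWFQNRRMKWKK
cpp047	KLAAALLKKWKKLAAALL
cpp048	KLALKALKALKAALKLA
cpp049	KLALKLALKALKAALK
cpp050	KLALKLALKALQAALQLA
cpp051	KLALKLALKAWKAALKLA
cpp052	KLALQLALQALQAALQLA
cpp053	KMTRAQRRAAARRNRWTAR
cpp054	KRPAATKKAGQAKKKKL
cpp055	LGTYTQDFNKFHTFPQTAIGVGAP
cpp056	LIRLWSHLIHIWFQNRRLKWKKK
cpp057	LKTLATALTKLAKTLTTL
cpp058	LKTLTETLKELTKTLTEL
cpp059	LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTESC
cpp060	LLIILRARIRKQAHAHSK
cpp061	LLIILRRPIRKQAHAHSK
cpp062	LLIILRRRIRKQAHAHSA
cpp063	LLIILRRRIRKQAHAHSK
cpp064	LNSAGYLLGKINLKALAALAKKIL
cpp065	LNSAGYLLGKLKALAALAKIL
cpp066	MANLGYWLLALFVTMWTDVGLCKKRPKP
cpp067	MDAQTRRRERRAEKQAQWKAAN
cpp068	MGLGLHLLVLAAALQGAKKKRKV
cpp069	MPKKKPTPIQLNP
cpp070	MVKSKIGSWILVLFVAMWSDVGLCKKRPKP
cpp071	MVTVLFRRLRIRRACGPPRVRV
cpp072	NAKTRRHERRRKLAIER
cpp073	PKKKRKV
cpp074	PKKKRKVALWKTLLKKVLKA
cpp075	PMLKE
cpp076	QLALQLALQALQAALQLA
cpp077	RGGRLSSYSRRRFSTSTGR
cpp078	RGGRLSYSRRRFSTSTGR
cpp079	RGGRLSYSRRRFSTSTGRA
cpp080	RKKRRQRRR
cpp081	RKSSKPIMEKRRRAR
cpp082	RQARRNRRRALWKTLLKKVLKA
cpp083	RQGAARVTSWLGRQLRIAGKRLEGR
cpp084	RQGAARVTSWLGRQLRIAGKRLEGRSK
cpp085	RQIKIWFPNRRMKWKK
cpp086	RQIKIWFQNMRRKWKK
cpp087	RQIKIWFQNRRMKWKK
cpp088	RQIKIWFQNRRMKWKKLRKKKKKH
cpp089	RQIRIWFQNRRMRWRR
cpp090	RQPKIWFPNRRMPWKK
cpp091	RRLSSYSSRRRF
cpp092	RRMKWKK
cpp093	RRRRRRRRR
cpp094	RRWRRWWRRWWRRWRR
cpp095	RVIRVWFQNKRCKDKK
cpp096	RVTSWLGRQLRIAGKRLEGRSK
cpp097	SWLGRQLRIAGKRLEGRSK
cpp098	TAKTRYKARRAELIAERR
cpp099	TRQARRNRRRWRERQR
cpp100	TRRNKRNRIQEQLNRK
cpp101	TRSSRAGLQFPVGRVHRLLRK
cpp102	TRSSRAGLQWPVGRVHRLLRKGGC
cpp103	VPALR
cpp104	VPMLK
cpp105	VPTLK
cpp106	VQAILRRNWNQYKIQ
cpp107	VRLPPPVRLPPPVRLPPP
cpp108	WFQNRRMKWKK
cpp109	YGRKKRRQRRR
cpp110	YGRKKRRQRRRGTSSSSDELSWIIELLEK
cpp111	YGRKKRRQRRRSVYDFFVWL
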