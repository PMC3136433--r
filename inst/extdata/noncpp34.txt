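# Known non-penetrating CPP analogs and peptide hormones (n=34)
ncpp01	AGCKNFFWKTFTSC
ncpp02	AHALCLTERQIKSNRRMKWKKEN
ncpp03	CYFQNCPRG
ncpp04	DFDMLRCMLGRVYRPCWQV
ncpp05	EILLPNNYNAYESYKYPGMFIALSK
ncpp06	FITKALGISYGRKKRRQC
ncpp07	FVPIFTHSELQKIREKERNKGQ
ncpp08	GRKKRRQPPQC
ncpp09	GWTLNSAGYLLGKFLPLILRKIVTAL
ncpp10	GWTLNSAGYLLGKINLKAPAALAKKIL
ncpp11	GWTLNSAGYLLGPHAI
ncpp12	GWTNLSAGYLLGPPPGFSPFR
ncpp13	HDEFERHAEGTFTSDVSSYLEGQAAKEFIAWLVKGR
ncpp14	IAARIKLRSRQHIKLRHL
ncpp15	ILRRRIRKQAHAHSK
ncpp16	KIWFQNRRMK
ncpp17	KKKQYTSIHHGVVEVD
ncpp18	KKLSECLKRIGDELDS
ncpp19	KLALKALKAALKLA
ncpp20	KLALKLALKALKAA
ncpp21	LLGKINLKALAALAKKIL
ncpp22	LLKTTALLKTTALLKTTA
ncpp23	LLKTTELLKTTELLKTTE
ncpp24	LNSAGYLLGKALAALAKKIL
ncpp25	LNSAGYLLGKLKALAALAK
ncpp26	LRKKKKKH
ncpp27	PVVHLTLRQAGDDFSR
ncpp28	QNLGNQWAVGHLM
ncpp29	RPPGFSPFR
ncpp30	RQIKIFFQNRRMKFKK
ncpp31	RQIKIWFQNRRM
ncpp32	RQIKIWFQNRRMKWK
ncpp33	TERQIKIWFQNRRMK
ncpp34	WSYGLRPG
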