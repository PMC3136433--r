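name	role	sequence	amidated
HIV-TAT	Control(+)	YGRKKRRQRRR	TRUE
Antennapedia	Control(+)	RQIKIWFQNRRMKWKK	TRUE
Pep-1	Control(+)	KETWWETWWTEWSQPKKKRKV	TRUE
negative-1	Control(-)	TCSSNCQTCPCSSNNCQ	TRUE
negative-2	Control(-)	GLALLGIAVAILVVL	TRUE
negative-3	Control(-)	PGNIQMMSVVSMSMTITN	TRUE
peptide-1	Predicted CPP	FKIYDKKVRTRVVKH	TRUE
peptide-2	Predicted CPP	RASKRDGSWVKKLHRILE	TRUE
peptide-3	Predicted CPP	KGTYKKKLMRIPLKGT	TRUE
peptide-4	Predicted CPP	LYKKGPAKKGRPPLRGWFH	TRUE
peptide-5	Predicted Non-CPP	FFSLPPVTQDWNSD	TRUE
peptide-6	Predicted Non-CPP	HSPIIPLGTRFVCHGVT	TRUE
TP13	Known Non-CPP-CPP Analog	LNSAGYLLGKALAALAKKIL	TRUE
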