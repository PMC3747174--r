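!gaf-version: 2.1
!generated for package examples
DB	geneA	geneA	 	GO:0000004	PMID:1	IEA	 	P	 	 	protein	taxon:9606	20200101	DB
DB	geneA	geneA	 	GO:0000004	PMID:2	IDA	 	P	 	 	protein	taxon:9606	20200101	DB
DB	geneB	geneB	NOT	GO:0000002	PMID:1	IDA	 	P	 	 	protein	taxon:9606	20200101	DB
DB	geneB	geneB	 	GO:0000003	PMID:1	IDA	 	P	 	 	protein	taxon:9606	20200101	DB
DB	geneC	geneC	 	GO:0000044	PMID:3	ISS	 	P	 	 	protein	taxon:9606	20200101	DB
malformed line without tabs
DB	geneD	geneD	 	GO:0000005	PMID:4	IEA	 	P	 	 	protein	taxon:9606	20200101	DB
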