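# gene	term
geneA	GO:0000004
geneB	GO:0000003
geneC	GO:0000044
geneC	GO:0000044
geneD	GO:0000005
geneE	GO:0000006
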