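taxon	phylum	lineages	genomes_with_tf	genomes_total	regulogs	regulons	tfs
Alphaproteobacteria	Proteobacteria	5	37	50	42	101	105
Betaproteobacteria	Proteobacteria	5	36	40	82	242	268
Gammaproteobacteria	Proteobacteria	10	67	90	81	203	208
Deltaproteobacteria	Proteobacteria	2	14	19	7	19	19
Firmicutes (Bacilli)	Firmicutes	6	35	54	22	60	64
Firmicutes (Clostridia)	Firmicutes	4	21	32	9	27	29
Actinobacteria	Actinobacteria	6	35	48	31	87	106
Bacteroidetes	Bacteroidetes	3	11	38	8	19	23
Deinococcus-Thermus	Deinococcus-Thermus	1	1	5	1	1	1
Cyanobacteria	Cyanobacteria	1	2	14	1	2	2
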