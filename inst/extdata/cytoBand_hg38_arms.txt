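chr1	0	121700000	p11	gneg
chr1	121700000	123400000	p11.1	acen
chr1	123400000	125100000	q11.1	acen
chr1	125100000	248956422	q11	gneg
chr2	0	91800000	p11	gneg
chr2	91800000	93900000	p11.1	acen
chr2	93900000	9.6e+07	q11.1	acen
chr2	9.6e+07	242193529	q11	gneg
chr3	0	87800000	p11	gneg
chr3	87800000	90900000	p11.1	acen
chr3	90900000	9.4e+07	q11.1	acen
chr3	9.4e+07	198295559	q11	gneg
chr4	0	48200000	p11	gneg
chr4	48200000	5e+07	p11.1	acen
chr4	5e+07	51800000	q11.1	acen
chr4	51800000	190214555	q11	gneg
chr5	0	46100000	p11	gneg
chr5	46100000	48800000	p11.1	acen
chr5	48800000	50700000	q11.1	acen
chr5	50700000	181538259	q11	gneg
chr6	0	58500000	p11	gneg
chr6	58500000	59800000	p11.1	acen
chr6	59800000	62600000	q11.1	acen
chr6	62600000	170805979	q11	gneg
chr7	0	58100000	p11	gneg
chr7	58100000	60100000	p11.1	acen
chr7	60100000	62100000	q11.1	acen
chr7	62100000	159345973	q11	gneg
chr8	0	43200000	p11	gneg
chr8	43200000	45200000	p11.1	acen
chr8	45200000	47200000	q11.1	acen
chr8	47200000	145138636	q11	gneg
chr9	0	42200000	p11	gneg
chr9	42200000	4.3e+07	p11.1	acen
chr9	4.3e+07	45500000	q11.1	acen
chr9	45500000	138394717	q11	gneg
chr10	0	3.8e+07	p11	gneg
chr10	3.8e+07	39800000	p11.1	acen
chr10	39800000	41600000	q11.1	acen
chr10	41600000	133797422	q11	gneg
chr11	0	5.1e+07	p11	gneg
chr11	5.1e+07	53400000	p11.1	acen
chr11	53400000	55800000	q11.1	acen
chr11	55800000	135086622	q11	gneg
chr12	0	33200000	p11	gneg
chr12	33200000	35500000	p11.1	acen
chr12	35500000	37800000	q11.1	acen
chr12	37800000	133275309	q11	gneg
chr13	0	16500000	p11	gneg
chr13	16500000	17700000	p11.1	acen
chr13	17700000	18900000	q11.1	acen
chr13	18900000	114364328	q11	gneg
chr14	0	16100000	p11	gneg
chr14	16100000	17200000	p11.1	acen
chr14	17200000	18200000	q11.1	acen
chr14	18200000	107043718	q11	gneg
chr15	0	17500000	p11	gneg
chr15	17500000	1.9e+07	p11.1	acen
chr15	1.9e+07	20500000	q11.1	acen
chr15	20500000	101991189	q11	gneg
chr16	0	35300000	p11	gneg
chr16	35300000	36800000	p11.1	acen
chr16	36800000	38400000	q11.1	acen
chr16	38400000	90338345	q11	gneg
chr17	0	22700000	p11	gneg
chr17	22700000	25100000	p11.1	acen
chr17	25100000	27400000	q11.1	acen
chr17	27400000	83257441	q11	gneg
chr18	0	15400000	p11	gneg
chr18	15400000	18500000	p11.1	acen
chr18	18500000	21500000	q11.1	acen
chr18	21500000	80373285	q11	gneg
chr19	0	24200000	p11	gneg
chr19	24200000	26200000	p11.1	acen
chr19	26200000	28100000	q11.1	acen
chr19	28100000	58617616	q11	gneg
chr20	0	25700000	p11	gneg
chr20	25700000	28100000	p11.1	acen
chr20	28100000	30400000	q11.1	acen
chr20	30400000	64444167	q11	gneg
chr21	0	10900000	p11	gneg
chr21	10900000	1.2e+07	p11.1	acen
chr21	1.2e+07	1.3e+07	q11.1	acen
chr21	1.3e+07	46709983	q11	gneg
chr22	0	13700000	p11	gneg
chr22	13700000	1.5e+07	p11.1	acen
chr22	1.5e+07	17400000	q11.1	acen
chr22	17400000	50818468	q11	gneg
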