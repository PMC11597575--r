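gene_id	symbol	regions	logFC_0C	logFC_4C	logFC_10C
At3g50380	AT3G50380	0C;4C;10C	13.1	12.6	10.2
At2g36850	GSL8	0C;4C;10C	12.8	12.2	8.1
At3g63460	SEC31B	0C;4C;10C	12.7	13.0	11.4
At4g00710	BSK3	0C;4C;10C	12.7	12.1	8.3
At1g21380	TOL3	0C;4C;10C	12.6	12.9	10.8
At5g17030	UGT78D3	0C;4C;10C	12.5	12.6	8.3
At2g02570	SPF30	0C;4C;10C	12.4	11.8	9.7
At3g54500	LNK2	0C;4C;10C	12.2	12.3	8.4
At5g47430	AT5G47430	0C;4C;10C	12.1	11.5	10.8
At3g55610	P5CS2	0C;4C;10C	11.9	11.7	8.5
At4g16990	RLM3	0C;4C;10C	11.9	11.8	10.8
At1g01060	LHY	0C;4C;10C	11.8	12.5	9.1
At5g62570	CBP60A	0C;4C;10C	11.7	11.0	9.8
At4g25450	ABCB28	0C;4C;10C	11.6	11.4	11.2
At2g42540	COR15A	0C;4C;10C	11.6	11.7	9.0
At5g37130	AT5G37130	0C;4C;10C	11.6	11.2	6.7
At4g36980	AT4G36980	0C;4C;10C	11.5	10.9	5.4
At2g23420	NAPRT2	0C;4C;10C	11.1	12.2	8.5
At3g57660	NRPA1	0C;4C;10C	11.1	10.5	10.6
At3g17609	HYH	0C;4C;10C	10.7	13.0	10.7
At1g80270	PPR596	0C;4C;10C	10.7	11.4	10.6
At5g20830	SUS1	0C;4C;10C	10.6	12.0	8.8
At3g25840	PRP4KA	0C;4C;10C	10.2	9.5	8.9
At1g11720	SS3	0C;4C;10C	10.0	9.9	10.7
At1g05200	GLR3.4	0C;4C;10C	9.5	11.0	11.4
At4g01985	AT4G01985	0C;4C;10C	9.5	9.2	6.7
At5g37260	CIR1	0C;4C;10C	9.3	7.6	5.8
At1g48540	AT1G48540	0C;4C;10C	9.1	9.3	8.2
At1g03080	NET1D	0C;4C;10C	8.6	8.7	7.7
At4g31210	AT4G31210	0C;4C;10C	8.3	9.8	10.1
At5g52310	LTI78	0C;4C;10C	8.0	8.2	5.3
At2g24560	GGL15	0C;4C	10.2	10.4	NA
At5g61380	TOC1	0C;4C	9.5	7.9	NA
At1g72440	EDA25	0C;4C	9.2	8.3	NA
At1g09350	Gols3	0C;4C	9.0	8.9	NA
At3g20810	JMJD5	0C;4C	8.8	7.8	NA
At4g33980	COR28	0C;4C	8.7	7.9	NA
At4g18422	At4g18422	0C;4C	8.2	7.3	NA
At2g42520	RH37	0C;4C	7.7	7.4	NA
At1g70640	At1g70640	0C;4C	7.7	7.5	NA
At3g51240	F3H	4C;10C	NA	10.1	7.5
At4g26530	FBA5	4C;10C	NA	9.5	10.6
At5g38410	RBCS3B	4C;10C	NA	8.5	8.3
At4g14690	ELIP2	4C;10C	NA	7.9	7.4
At3g63340	AT3G63340	4C;10C	NA	7.7	6.7
At5g35210	PTM	4C;10C	NA	7.6	5.8
At5g27970	At5g27970	4C;10C	NA	7.4	6.5
At4g04850	KEA3	4C;10C	NA	7.4	5.9
At1g34260	FAB1D	0C;10C	8.5	NA	5.6
At1g30620	MUR4	0C;10C	8.4	NA	5.6
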