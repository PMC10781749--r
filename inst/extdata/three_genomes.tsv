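genome_id	replicon_id	start	end	strand	locus_tag	component	score
gA	gA_c1	1	900	+	gA_0001		
gA	gA_c1	1001	1900	-	gA_0002		
gA	gA_c1	2001	2900	+	gA_0003		
gA	gA_c1	3001	3900	-	gA_0004		
gA	gA_c1	4001	4900	+	gA_0005		
gA	gA_c1	5001	5900	-	gA_0006		
gA	gA_c1	6001	6900	+	gA_0007		
gA	gA_c1	7001	7900	-	gA_0008		
gA	gA_c1	8001	8900	+	gA_0009		
gA	gA_c1	9001	9900	-	gA_0010		
gA	gA_c1	10001	10900	+	gA_0011	TssB	80
gA	gA_c1	11001	11900	-	gA_0012	TssC	80
gA	gA_c1	12001	12900	+	gA_0013	TssD	80
gA	gA_c1	13001	13900	-	gA_0014	TssE	80
gA	gA_c1	14001	14900	+	gA_0015	TssF	80
gA	gA_c1	15001	15900	-	gA_0016	TssG	80
gA	gA_c1	16001	16900	+	gA_0017	TssH	80
gA	gA_c1	17001	17900	-	gA_0018	TssI	80
gA	gA_c1	18001	18900	+	gA_0019	TssK	80
gA	gA_c1	19001	19900	-	gA_0020	TssN	80
gA	gA_c1	20001	20900	+	gA_0021	TssO	80
gA	gA_c1	21001	21900	-	gA_0022	TssP	80
gA	gA_c1	22001	22900	+	gA_0023	TssQ	80
gA	gA_c1	23001	23900	-	gA_0024	TssR	80
gA	gA_c1	24001	24900	+	gA_0025		
gA	gA_c1	25001	25900	-	gA_0026		
gA	gA_c1	26001	26900	+	gA_0027		
gA	gA_c1	27001	27900	-	gA_0028		
gA	gA_c1	28001	28900	+	gA_0029		
gA	gA_c1	29001	29900	-	gA_0030		
gA	gA_c1	30001	30900	+	gA_0031		
gA	gA_c1	31001	31900	-	gA_0032		
gA	gA_c1	32001	32900	+	gA_0033		
gA	gA_c1	33001	33900	-	gA_0034		
gA	gA_c1	34001	34900	+	gA_0035		
gA	gA_c1	35001	35900	-	gA_0036		
gA	gA_c1	36001	36900	+	gA_0037		
gA	gA_c1	37001	37900	-	gA_0038		
gA	gA_c1	38001	38900	+	gA_0039		
gA	gA_c1	39001	39900	-	gA_0040		
gA	gA_c1	40001	40900	+	gA_0041		
gA	gA_c1	41001	41900	-	gA_0042		
gA	gA_c1	42001	42900	+	gA_0043		
gA	gA_c1	43001	43900	-	gA_0044		
gA	gA_c1	44001	44900	+	gA_0045		
gA	gA_c1	45001	45900	-	gA_0046		
gA	gA_c1	46001	46900	+	gA_0047		
gA	gA_c1	47001	47900	-	gA_0048		
gA	gA_c1	48001	48900	+	gA_0049		
gA	gA_c1	49001	49900	-	gA_0050		
gA	gA_c1	50001	50900	+	gA_0051		
gA	gA_c1	51001	51900	-	gA_0052		
gA	gA_c1	52001	52900	+	gA_0053		
gA	gA_c1	53001	53900	-	gA_0054		
gA	gA_c1	54001	54900	+	gA_0055		
gA	gA_c1	55001	55900	-	gA_0056		
gA	gA_c1	56001	56900	+	gA_0057		
gA	gA_c1	57001	57900	-	gA_0058		
gA	gA_c1	58001	58900	+	gA_0059		
gA	gA_c1	59001	59900	-	gA_0060		
gB	gB_c1	1	900	+	gB_0001		
gB	gB_c1	1001	1900	-	gB_0002		
gB	gB_c1	2001	2900	+	gB_0003		
gB	gB_c1	3001	3900	-	gB_0004		
gB	gB_c1	4001	4900	+	gB_0005		
gB	gB_c1	5001	5900	-	gB_0006	TssB	80
gB	gB_c1	6001	6900	+	gB_0007	TssC	80
gB	gB_c1	7001	7900	-	gB_0008	TssD	80
gB	gB_c1	8001	8900	+	gB_0009	TssE	80
gB	gB_c1	9001	9900	-	gB_0010	TssF	80
gB	gB_c1	10001	10900	+	gB_0011	TssG	80
gB	gB_c1	11001	11900	-	gB_0012	TssH	80
gB	gB_c1	12001	12900	+	gB_0013		
gB	gB_c1	13001	13900	-	gB_0014		
gB	gB_c1	14001	14900	+	gB_0015		
gB	gB_c1	15001	15900	-	gB_0016		
gB	gB_c1	16001	16900	+	gB_0017		
gB	gB_c1	17001	17900	-	gB_0018		
gB	gB_c1	18001	18900	+	gB_0019		
gB	gB_c1	19001	19900	-	gB_0020		
gB	gB_c1	20001	20900	+	gB_0021		
gB	gB_c1	21001	21900	-	gB_0022		
gB	gB_c1	22001	22900	+	gB_0023		
gB	gB_c1	23001	23900	-	gB_0024		
gB	gB_c1	24001	24900	+	gB_0025		
gB	gB_c1	25001	25900	-	gB_0026		
gB	gB_c1	26001	26900	+	gB_0027		
gB	gB_c1	27001	27900	-	gB_0028		
gB	gB_c1	28001	28900	+	gB_0029		
gB	gB_c1	29001	29900	-	gB_0030		
gB	gB_c1	30001	30900	+	gB_0031		
gB	gB_c1	31001	31900	-	gB_0032		
gB	gB_c1	32001	32900	+	gB_0033		
gB	gB_c1	33001	33900	-	gB_0034		
gB	gB_c1	34001	34900	+	gB_0035		
gB	gB_c1	35001	35900	-	gB_0036		
gB	gB_c1	36001	36900	+	gB_0037		
gB	gB_c1	37001	37900	-	gB_0038		
gB	gB_c1	38001	38900	+	gB_0039		
gB	gB_c1	39001	39900	-	gB_0040		
gB	gB_c1	40001	40900	+	gB_0041	TssI	80
gB	gB_c1	41001	41900	-	gB_0042	TssK	80
gB	gB_c1	42001	42900	+	gB_0043	TssN	80
gB	gB_c1	43001	43900	-	gB_0044	TssO	80
gB	gB_c1	44001	44900	+	gB_0045	TssP	80
gB	gB_c1	45001	45900	-	gB_0046	TssQ	80
gB	gB_c1	46001	46900	+	gB_0047	TssR	80
gB	gB_c1	47001	47900	-	gB_0048		
gB	gB_c1	48001	48900	+	gB_0049		
gB	gB_c1	49001	49900	-	gB_0050		
gB	gB_c1	50001	50900	+	gB_0051		
gB	gB_c1	51001	51900	-	gB_0052		
gB	gB_c1	52001	52900	+	gB_0053		
gB	gB_c1	53001	53900	-	gB_0054		
gB	gB_c1	54001	54900	+	gB_0055		
gB	gB_c1	55001	55900	-	gB_0056		
gB	gB_c1	56001	56900	+	gB_0057		
gB	gB_c1	57001	57900	-	gB_0058		
gB	gB_c1	58001	58900	+	gB_0059		
gB	gB_c1	59001	59900	-	gB_0060		
gC	gC_c1	1	900	+	gC_0001		
gC	gC_c1	1001	1900	-	gC_0002		
gC	gC_c1	2001	2900	+	gC_0003		
gC	gC_c1	3001	3900	-	gC_0004		
gC	gC_c1	4001	4900	+	gC_0005		
gC	gC_c1	5001	5900	-	gC_0006		
gC	gC_c1	6001	6900	+	gC_0007		
gC	gC_c1	7001	7900	-	gC_0008		
gC	gC_c1	8001	8900	+	gC_0009		
gC	gC_c1	9001	9900	-	gC_0010		
gC	gC_c1	10001	10900	+	gC_0011		
gC	gC_c1	11001	11900	-	gC_0012		
gC	gC_c1	12001	12900	+	gC_0013		
gC	gC_c1	13001	13900	-	gC_0014		
gC	gC_c1	14001	14900	+	gC_0015		
gC	gC_c1	15001	15900	-	gC_0016		
gC	gC_c1	16001	16900	+	gC_0017		
gC	gC_c1	17001	17900	-	gC_0018		
gC	gC_c1	18001	18900	+	gC_0019		
gC	gC_c1	19001	19900	-	gC_0020		
gC	gC_c1	20001	20900	+	gC_0021	TssB	80
gC	gC_c1	21001	21900	-	gC_0022	TssC	80
gC	gC_c1	22001	22900	+	gC_0023	TssD	80
gC	gC_c1	23001	23900	-	gC_0024	TssN	80
gC	gC_c1	24001	24900	+	gC_0025	TssP	80
gC	gC_c1	25001	25900	-	gC_0026		
gC	gC_c1	26001	26900	+	gC_0027		
gC	gC_c1	27001	27900	-	gC_0028		
gC	gC_c1	28001	28900	+	gC_0029		
gC	gC_c1	29001	29900	-	gC_0030		
gC	gC_c1	30001	30900	+	gC_0031		
gC	gC_c1	31001	31900	-	gC_0032		
gC	gC_c1	32001	32900	+	gC_0033		
gC	gC_c1	33001	33900	-	gC_0034		
gC	gC_c1	34001	34900	+	gC_0035		
gC	gC_c1	35001	35900	-	gC_0036		
gC	gC_c1	36001	36900	+	gC_0037		
gC	gC_c1	37001	37900	-	gC_0038		
gC	gC_c1	38001	38900	+	gC_0039		
gC	gC_c1	39001	39900	-	gC_0040		
gC	gC_c1	40001	40900	+	gC_0041		
gC	gC_c1	41001	41900	-	gC_0042		
gC	gC_c1	42001	42900	+	gC_0043		
gC	gC_c1	43001	43900	-	gC_0044		
gC	gC_c1	44001	44900	+	gC_0045		
gC	gC_c1	45001	45900	-	gC_0046		
gC	gC_c1	46001	46900	+	gC_0047		
gC	gC_c1	47001	47900	-	gC_0048		
gC	gC_c1	48001	48900	+	gC_0049		
gC	gC_c1	49001	49900	-	gC_0050		
gC	gC_c1	50001	50900	+	gC_0051		
gC	gC_c1	51001	51900	-	gC_0052		
gC	gC_c1	52001	52900	+	gC_0053		
gC	gC_c1	53001	53900	-	gC_0054		
gC	gC_c1	54001	54900	+	gC_0055		
gC	gC_c1	55001	55900	-	gC_0056		
gC	gC_c1	56001	56900	+	gC_0057		
gC	gC_c1	57001	57900	-	gC_0058		
gC	gC_c1	58001	58900	+	gC_0059		
gC	gC_c1	59001	59900	-	gC_0060		
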