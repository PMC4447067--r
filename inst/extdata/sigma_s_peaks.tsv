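table	peak_start	peak_end	gene_id	strand	tss	sigmaS_evidence	category_truth
T1	63400	63538	hepA	-		FALSE	unequivocal
T1	106436	106616	lpxC	+	106530	TRUE	unequivocal
T1	262040	262202	thrW	+		FALSE	unequivocal
T1	392250	392349	insEF-2	-		TRUE	unequivocal
T1	406100	406199	yaiA	+		TRUE	unequivocal
T1	437329	437469	yajO	-		TRUE	unequivocal
T1	479920	480115	tomB	-		FALSE	unequivocal
T1	574850	575099	insH-2	-		FALSE	unequivocal
T1	837550	837849	ybiI	-		FALSE	unequivocal
T1	848050	848349	dps	-	848173	TRUE	unequivocal
T1	1215900	1216399	ymgC	+		TRUE	unequivocal
T1	1219400	1219949	ycgH	NA		FALSE	unequivocal
T1	1236420	1236526	ycgB	-	1236508	TRUE	unequivocal
T1	1341304	1341480	osmB	-	1341393	TRUE	unequivocal
T1	1430250	1430549	tfaR	+		FALSE	unequivocal
T1	1509526	1509697	ydcS	+	1509623	TRUE	unequivocal
T1	1524000	1524199	ansP	-	1524035,1524044	TRUE	unequivocal
T1	1608700	1608949	uxaB	-	1608744	FALSE	unequivocal
T1	1687744	1687907	ydgA	+	1687818	TRUE	unequivocal
T1	1755350	1755499	lpp	+	1755407	FALSE	unequivocal
T1	1756820	1756885	ynhG	-		TRUE	unequivocal
T1	1894663	1894896	sdaA	+	1894833	FALSE	unequivocal
T1	1905547	1905784	yobF	-	1905641	FALSE	unequivocal
T1	1920033	1920203	yebW	+		FALSE	unequivocal
T1	1921150	1921299	ryeB	-		TRUE	unequivocal
T1	2026384	2026505	yodC	-		TRUE	unequivocal
T1	2061261	2061484	erfK	-		TRUE	unequivocal
T1	2103850	2104199	wbbI	-		FALSE	unequivocal
T1	2104550	2105599	wbbH	-		FALSE	unequivocal
T1	2190800	2190949	yehE	-		FALSE	unequivocal
T1	2225279	2225390	yohF	-		TRUE	unequivocal
T1	2468677	2468882	tfaS	+		FALSE	unequivocal
T1	2663364	2663501	csiE	+	2663423	TRUE	unequivocal
T1	2734910	2735081	raiA	+		TRUE	unequivocal
T1	2753502	2753707	ssrA	+	2753608	FALSE	unequivocal
T1	2758300	2758999	yfjJ	+		TRUE	unequivocal
T1	2797100	2797249	alaE	+		FALSE	unequivocal
T1	2817227	2817395	csrA	-	2817295	TRUE	unequivocal
T1	2924252	2924370	ygdH	+		TRUE	unequivocal
T1	2974153	2974278	omrA	-	2974211	TRUE	unequivocal
T1	2991100	2992299	ygeI	+		FALSE	unequivocal
T1	3054792	3054952	sibC	+	3054873	FALSE	unequivocal
T1	3058600	3058749	scpA	+		FALSE	unequivocal
T1	3066050	3066149	yggE	-	3066148	TRUE	unequivocal
T1	3235233	3235381	ygjR	+	3235304	FALSE	unequivocal
T1	3598950	3599099	rpoH	-		TRUE	unequivocal
T1	3637750	3637949	uspB	-	3637871	TRUE	unequivocal
T1	3706750	3706999	proK	-		FALSE	unequivocal
T1	4361287	4361432	yjdC	-	4361353	TRUE	unequivocal
T1	4437000	4437349	ytfJ	-	4437309	TRUE	unequivocal
T2	1257750	1258199	pth	-	1257765	FALSE	divergent
T2	1257750	1258199	ychH	+	1257961	TRUE	divergent
T2	1288250	1288399	ychJ	-	1288400	FALSE	divergent
T2	1288250	1288399	rssA	+	1288329	TRUE	divergent
T2	1438800	1439049	ydbK	-		FALSE	divergent
T2	1438800	1439049	ydbJ	+	1439053	FALSE	divergent
T2	1488650	1488949	gapC_1	-		TRUE	divergent
T2	1488650	1488949	cybB	+		FALSE	divergent
T2	1820250	1820349	osmE	-	1820307	TRUE	divergent
T2	1820250	1820349	nadE	+	1820326	FALSE	divergent
T2	2022850	2023149	dsrB	-		TRUE	divergent
T2	2022850	2023149	yodD	+		TRUE	divergent
T2	2493450	2493549	yfdY	-		FALSE	divergent
T2	2493450	2493549	lpxP	+		TRUE	divergent
T2	2627100	2627399	yfgF	-		FALSE	divergent
T2	2627100	2627399	yfgG	+	2627275	FALSE	divergent
T2	2903350	2903649	queE	-		FALSE	divergent
T2	2903350	2903649	ygcG	+		TRUE	divergent
T2	3851100	3851399	istR-1/istR-2	-	3851215,3851280	FALSE	divergent
T2	3851100	3851399	tisB	+	3851360	FALSE	divergent
T2	4124850	4125049	priA	-		FALSE	divergent
T2	4124850	4125049	rpmE	+	4124931	FALSE	divergent
T2	4414650	4414899	bsmA	-		TRUE	divergent
T2	4414650	4414899	yjfP	+		FALSE	divergent
T2	4434400	4434749	cpdB	-	4434652	FALSE	divergent
T2	4434400	4434749	cysQ	+		FALSE	divergent
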