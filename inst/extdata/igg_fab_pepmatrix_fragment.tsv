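MH+	time (s)	Peak intensity in sample 1	Peak intensity in sample 2	Peak intensity in sample 3	Peptide present in sample 1	Peptide present in sample 2	Peptide present in sample 3	Total count of peptides
1238.712	5702.29	30528	25175	23642	1	1	1	3
1238.735	7770.22	12416	9487	7326	1	1	1	3
1238.899	713.267	7848	5629	6229	1	1	1	3
1239.259	7969.383	10005	13333	19683	1	1	1	3
1239.53	4314.73	7110	10243	7283	1	1	1	3
1239.597	8150.09	5207	6428	2798	1	1	1	3
1239.599	4408.91	8264	7158	6992	1	1	1	3
1239.601	7048.683	4542	8373	6982	1	1	1	3
1239.621	1190.17	370540	333496	302810	1	1	1	3
1239.622	6657.29	69391	66874	53379	1	1	1	3
1239.624	5446.54	26198	32726	20632	1	1	1	3
1239.635	4654.07	60855	59416	159055	1	1	1	3
1239.638	6675.558	10973	0	14356	1	0	1	2
1239.64	3143.02	6429	6080	5409	1	1	1	3
1239.642	5808.01	192225	191568	159055	1	1	1	3
1239.692	4271.67	256980	297801	209433	1	1	1	3
1239.734	10051	6161	6481	5449	1	1	1	3
1239.749	7239.35	18034	14470	16265	1	1	1	3
1239.75	6547.471	7043	8459	5901	1	1	1	3
1240.065	5805.98	14427	14851	6499	1	1	1	3
1240.098	5509.82	19378	25322	20168	1	1	1	3
1240.499	2631.25	17863	9718	15101	1	1	1	3
1240.521	4792.05	15576	14008	16506	1	1	1	3
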