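Locus	Chromosome	He	Ho	Nei	Ae	I
Indel1-4	1	0.859	0.141	0.1406	1.1636	0.2691
Indel1-9	1	0.9892	0.0108	0.0108	1.0109	0.0338
RM10716	1	0.8727	0.1273	0.127	1.15	0.2428
Indel2-4	2	0.8498	0.1502	0.1498	1.1761	0.2825
Indel2-3	2	0.8205	0.1796	0.1791	1.2432	0.3066
RM12923	2	0.8518	0.1482	0.1478	1.1978	0.2559
RM13406	2	0.5024	0.4976	0.4962	1.985	0.6894
Indel3-7	3	0.8835	0.1165	0.1162	1.1371	0.225
Indel3-23	3	0.9784	0.0216	0.0215	1.022	0.06
RM14759	3	0.8408	0.1592	0.1588	1.1888	0.2954
RM15347	3	0.5982	0.4018	0.4007	1.6686	0.5903
Indel4-3	4	0.8683	0.1317	0.1313	1.1512	0.2553
Indel4-10	4	0.9784	0.0216	0.0215	1.022	0.06
RM16555	4	0.9053	0.0947	0.0945	1.1083	0.1915
RM5424	4	0.8057	0.1943	0.1938	1.2403	0.3438
Indel5-2	5	0.9784	0.0216	0.0215	1.022	0.06
Indel5-9	5	0.7972	0.2028	0.2022	1.2535	0.3551
RM18502	5	0.8683	0.1317	0.1313	1.1512	0.2553
Indel6-4	6	0.8498	0.1502	0.1498	1.1761	0.2825
Indel6-9	6	0.8748	0.1252	0.1249	1.1467	0.241
RM19725	6	0.9367	0.0633	0.0631	1.0673	0.1437
RM20111	6	0.9784	0.0216	0.0215	1.022	0.06
Indel7-5	7	0.8057	0.1943	0.1938	1.2403	0.3438
Indel7-9	7	0.8173	0.1827	0.1822	1.2493	0.3112
RM21236	7	0.8408	0.1592	0.1588	1.1888	0.2954
Indel8-3	8	0.9784	0.0216	0.0215	1.022	0.06
Indel8-8	8	0.947	0.053	0.0529	1.0558	0.1248
RM22959	8	0.9784	0.0216	0.0215	1.022	0.06
Indel9-2	9	0.8683	0.1317	0.1313	1.1512	0.2553
Indel9-8	9	0.9241	0.0759	0.0757	1.0873	0.1515
RM23842	9	0.6531	0.3469	0.3459	1.5547	0.5255
Indel10-6	10	0.7807	0.2193	0.2188	1.28	0.3768
Indel10-8	10	0.9626	0.0374	0.0373	1.0388	0.094
RM25375	10	0.6698	0.3302	0.3293	1.5197	0.5051
Indel11-4	11	0.7461	0.2539	0.2533	1.3924	0.3944
Indel11-9	11	0.8873	0.1127	0.1124	1.1267	0.2264
RM26319	11	0.8407	0.1593	0.1589	1.2266	0.2675
Indel12-3	12	0.8172	0.1828	0.1823	1.2297	0.3242
Indel12-9	12	0.9383	0.0618	0.0616	1.0688	0.1301
RM28107	12	0.7279	0.2721	0.2714	1.4008	0.4352
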