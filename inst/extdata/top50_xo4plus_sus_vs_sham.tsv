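Gene symbol	logFC	AvgExp	t	Pval	adj PVal	B
Birc5	5.76502	1.7672889	9.02935	2.22E‐10	3.14E‐07	13.48506
Cdkn3	5.64183	1.5432145	6.744088	1.18E‐07	3.49E‐05	7.515466
Kif11	5.49926	0.2461131	6.576116	1.91E‐07	5.14E‐05	6.97426
Ncapg	5.47342	−0.1786981	5.464827	4.88E‐06	5.93E‐04	3.988828
Cdc20	5.45743	1.0739871	7.403038	1.82E‐08	8.52E‐06	9.133173
Nuf2	5.32476	−0.3289444	6.736156	1.21E‐07	3.49E‐05	7.284114
Ccnb2	5.2893	1.9141487	7.553196	1.19E‐08	6.74E‐06	9.804982
Aurkb	5.28106	0.1698159	7.026936	5.26E‐08	2.05E‐05	8.075848
Cit	5.24623	0.3082589	6.415315	3.04E‐07	7.16E‐05	6.501784
Hmmr	5.22306	1.186993	7.569951	1.14E‐08	6.74E‐06	9.797002
Esco2	5.20983	1.0709507	4.81764	3.25E‐05	2.80E‐03	2.353105
Melk	5.17911	−0.554891	6.172445	6.16E‐07	1.18E‐04	5.824797
Cdc25c	5.17482	−0.7504202	5.556821	3.73E‐06	4.68E‐04	4.188965
Kif23	5.13702	0.6650897	6.945323	6.63E‐08	2.30E‐05	7.956364
Nek2	5.09204	−0.8391415	5.851377	1.57E‐06	2.54E‐04	4.972077
Troap	5.07497	−1.0475974	7.38968	1.89E‐08	8.52E‐06	8.82398
Dlgap5	5.0637	−0.3794831	6.798489	1.01E‐07	3.16E‐05	7.445236
Tk1	5.06171	1.4926731	7.504487	1.37E‐08	7.36E‐06	9.280781
Mcm10	5.04637	−1.0895909	7.260236	2.71E‐08	1.10E‐05	8.355957
Saa3	4.93308	−1.1465763	5.045849	1.67E‐05	1.68E‐03	2.844773
Plac8	4.9074	1.316802	5.889764	1.40E‐06	2.33E‐04	5.218269
Clspn	4.87938	1.3914605	6.258953	4.79E‐07	9.81E‐05	6.258822
Mki67	4.81598	2.6575306	7.401992	1.82E‐08	8.52E‐06	9.451222
Cenpk	4.81418	1.0168275	6.273493	4.59E‐07	9.60E‐05	6.240974
Casc5	4.79524	1.9047316	6.021465	9.56E‐07	1.71E‐04	5.65795
Ccnb1	4.78376	0.8942972	8.35344	1.33E‐09	1.33E‐06	11.79537
Ndc80	4.77516	0.9359373	6.74738	1.17E‐07	3.49E‐05	7.549301
Aspm	4.77431	0.7784471	6.30262	4.22E‐07	8.98E‐05	6.4019
Mns1	4.77059	−0.9456452	5.116901	1.35E‐05	1.40E‐03	2.98948
Stil	4.71375	−0.4286108	6.896241	7.63E‐08	2.46E‐05	7.747276
Ankle1	4.70824	−0.8978755	5.791278	1.87E‐06	2.91E‐04	4.711205
Spc24	4.69279	1.3423116	8.911432	3.03E‐10	3.80E‐07	12.94538
Gpsm2	4.65782	−0.7681863	5.503262	4.36E‐06	5.35E‐04	4.048151
Prc1	4.6556	2.8666675	9.092631	1.89E‐10	3.04E‐07	13.79044
Cenpi	4.63601	0.7782963	5.284361	8.29E‐06	9.00E‐04	3.53967
Rab13	4.6245	−0.436683	5.777597	1.95E‐06	2.91E‐04	4.733482
Cep55	4.61759	0.1648057	6.537217	2.14E‐07	5.62E‐05	6.96793
Hist1h2ae	4.61674	0.6086809	5.236377	9.54E‐06	1.03E‐03	3.448414
Cdc6	4.59923	−0.7363785	5.380778	6.25E‐06	7.20E‐04	3.650384
Foxm1	4.57058	0.2001768	4.66003	5.15E‐05	4.18E‐03	1.887387
Sgol2a	4.56722	0.8256839	5.301333	7.89E‐06	8.65E‐04	3.661214
Tpx2	4.5441	1.3968306	6.899334	7.56E‐08	2.46E‐05	8.057218
Shcbp1	4.5333	−0.2503641	6.219989	5.36E‐07	1.06E‐04	6.048152
Chaf1a	4.5075	−0.3486608	4.197819	1.95E‐04	1.29E‐02	0.699981
Sgol1	4.50239	1.1036653	6.068962	8.32E‐07	1.54E‐04	5.751895
Ckap2l	4.49338	2.7278769	7.949218	3.99E‐09	3.22E‐06	10.8567
Rad51ap1	4.43737	1.7528958	5.761704	2.04E‐06	3.00E‐04	4.897387
C330027C09Rik	4.41274	1.2903056	4.872646	2.77E‐05	2.50E‐03	2.500517
Ccnf	4.38312	0.9642677	5.68638	2.55E‐06	3.43E‐04	4.605822
Ckap2	4.37671	0.4264924	5.925534	1.26E‐06	2.20E‐04	5.33635
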