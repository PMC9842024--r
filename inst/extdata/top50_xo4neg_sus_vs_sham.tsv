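Gene symbol	logFC	AvgExp	t	Pval	adj PVal	B
Ccnb2	7.2434	1.914149	8.71212	5.11E‐10	7.22E‐07	12.5665
Mki67	6.99802	2.657531	7.78265	6.32E‐09	4.76E‐06	10.315
Cep55	6.79948	0.164806	7.8447	5.32E‐09	4.30E‐06	9.96164
Nek2	6.41184	−0.839141	6.86382	8.37E‐08	3.50E‐05	7.42704
Hmmr	6.18986	1.186993	7.24982	2.80E‐08	1.46E‐05	8.78338
Birc5	6.08931	1.767289	8.46022	1.00E‐09	1.26E‐06	11.9784
Troap	5.92187	−1.047597	7.56325	1.16E‐08	7.71E‐06	8.95771
Tpx2	5.87434	1.396831	7.53024	1.27E‐08	7.99E‐06	9.61853
Dlgap5	5.72789	−0.379483	7.32031	2.29E‐08	1.29E‐05	8.68108
Stil	5.71934	−0.428611	7.04233	5.03E‐08	2.37E‐05	7.82959
Aurkb	5.68337	0.169816	6.6225	1.67E‐07	5.90E‐05	6.88724
Pbk	5.614	0.578285	6.5491	2.07E‐07	6.86E‐05	6.79667
Ttk	5.56047	−0.003396	6.1612	6.36E‐07	1.75E‐04	5.66954
Fam64a	5.54815	0.172748	5.54325	3.88E‐06	7.30E‐04	4.21982
Bub1b	5.52541	0.852802	5.58235	3.46E‐06	6.62E‐04	4.21705
Aspm	5.49894	0.778447	6.00626	9.99E‐07	2.52E‐04	5.51711
Plk1	5.4907	0.714941	6.32957	3.90E‐07	1.16E‐04	6.2301
Plac8	5.4786	1.316802	5.79718	1.84E‐06	4.24E‐04	4.89829
Kif18b	5.41274	−0.920601	6.03763	9.12E‐07	2.39E‐04	5.27128
Kif23	5.40663	0.66509	6.66974	1.46E‐07	5.45E‐05	7.16429
Top2a	5.32157	3.363108	8.73594	4.80E‐10	7.22E‐07	12.923
Psrc1	5.32146	−1.473526	6.94318	6.67E‐08	2.90E‐05	7.27514
Cenpe	5.27386	3.005189	10.3774	7.47E‐12	1.88E‐08	16.8919
Melk	5.20793	−0.554891	5.49586	4.46E‐06	7.99E‐04	3.98286
Brca1	5.19986	−0.261344	5.04746	1.66E‐05	2.15E‐03	2.80218
Ccnb1	5.13942	0.894297	7.24474	2.84E‐08	1.46E‐05	8.78185
Cit	5.12791	0.308259	5.3118	7.65E‐06	1.17E‐03	3.51658
Ccdc158	5.11777	−1.673486	5.38333	6.20E‐06	1.08E‐03	3.52871
Ndc80	5.07311	0.935937	5.73685	2.20E‐06	4.78E‐04	4.73085
Kif4	5.04925	−0.560068	5.2436	9.34E‐06	1.37E‐03	3.39874
Cenpm	5.04778	0.457076	6.94527	6.63E‐08	2.90E‐05	7.85063
Efcab11	4.93682	−1.413903	4.9978	1.92E‐05	2.38E‐03	2.61281
Sgol2a	4.93232	0.825684	4.83884	3.06E‐05	3.63E‐03	2.39082
Casc5	4.8797	1.904732	5.80704	1.79E‐06	4.21E‐04	5.06427
Cdkn3	4.84763	1.543214	6.66124	1.50E‐07	5.45E‐05	7.39483
Ncapg	4.83529	−0.178698	4.56748	6.73E‐05	6.29E‐03	1.65013
Arfgap3	−4.8143	3.227787	−4.82253	3.21E‐05	3.68E‐03	1.97355
Cdca3	4.8047	1.033934	5.83682	1.64E‐06	4.03E‐04	5.09039
Polr3g	−4.8016	2.483651	−3.08136	4.17E‐03	1.20E‐01	‐1.94254
Nuf2	4.79014	−0.328944	5.16747	1.17E‐05	1.63E‐03	3.13439
Kif11	4.76106	0.246113	5.80768	1.79E‐06	4.21E‐04	4.99501
Pilrb1	4.75962	−0.129751	4.35596	1.24E‐04	1.03E‐02	1.05207
Fxyd6	4.71611	−1.097719	4.32485	1.36E‐04	1.09E‐02	0.93726
Rrm2	4.71417	1.554915	6.78453	1.05E‐07	4.09E‐05	7.67497
Kif14	4.65924	−1.058188	5.27195	8.60E‐06	1.28E‐03	3.28961
Spc25	4.65365	1.777619	5.18905	1.10E‐05	1.56E‐03	3.34028
Omd	4.62121	1.038544	5.63473	2.96E‐06	5.98E‐04	4.39438
Cdca2	4.61168	1.731777	8.22232	1.90E‐09	1.95E‐06	11.4262
Knstrn	4.60604	1.515975	6.81994	9.48E‐08	3.83E‐05	7.75424
Cdc20	4.46665	1.073987	6.07832	8.10E‐07	2.18E‐04	5.73238
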