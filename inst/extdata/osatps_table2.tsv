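s_no	gene_code	subfamily	protein_length	gene_gi	organism
1	OsaTPS1	TPSa	507	75251482	Ocimum basilicum
2	OsaTPS2	TPSa	535	75251483	Ocimum basilicum
3	OsaTPS3	TPSa	320	939319666	Solanum lycopersicum
4	OsaTPS4	TPSa	577	75267592	Solanum tuberosum
5	OsaTPS5	TPSa	566	75251484	Ocimum basilicum
6	OsaTPS6	TPSa	383	403399735	Origanum vulgare
7	OsaTPS7	TPSa	545	122219293	Pogostemon cablin
8	OsaTPS8	TPSa	550	122219293	Pogostemon cablin
9	OsaTPS9	TPSa	543	122219293	Pogostemon cablin
10	OsaTPS10	TPSa	540	476007192	Phyla dulcis
11	OsaTPS11	TPSa	521	75251482	Ocimum basilicum
12	OsaTPS12	TPSa	551	75251484	Ocimum basilicum
13	OsaTPS13	TPSa	468	476007821	Hyoscyamus muticus
14	OsaTPS14	TPSa	383	75252096	Mentha x piperita
15	OsaTPS15	TPSa	274	122219293	Pogostemon cablin
16	OsaTPS16	TPSa	379	75252096	Mentha x piperita
17	OsaTPS17	TPSa	507	75251484	Ocimum basilicum
18	OsaTPS18	TPSa	388	75251482	Ocimum basilicum
19	OsaTPS19	TPSb	533	75232269	Populus tremuloides
20	OsaTPS20	TPSb	530	487524480	Ricinus communis
21	OsaTPS21	TPSb	316	487524480	Ricinus communis
22	OsaTPS22	TPSb	546	476007226	Phyla dulcis
23	OsaTPS23	TPSb	512	75251481	Ocimum basilicum
24	OsaTPS24	TPSb	558	122210944	Lavandula angustifolia
25	OsaTPS25	TPSb	356	62900763	Salvia officinalis
26	OsaTPS26	TPSb	524	122210944	Lavandula angustifolia
27	OsaTPS27	TPSb	589	62900763	Salvia officinalis
28	OsaTPS28	TPSb	575	62900763	Salvia officinalis
29	OsaTPS29	TPSb	622	75251478	Ocimum basilicum
30	OsaTPS30	TPSb	650	75251478	Ocimum basilicum
31	OsaTPS31	TPSb	350	75251477	Ocimum basilicum
32	OsaTPS32	TPSb	512	75251477	Ocimum basilicum
33	OsaTPS33	TPSb	601	75251479	Ocimum basilicum
34	OsaTPS34	TPSb	556	75251479	Ocimum basilicum
35	OsaTPS35	TPSc	826	62900382	Pisum sativum
36	OsaTPS36	TPSc	783	62900382	Pisum sativum
37	OsaTPS37	TPSc	824	544602148	Nicotiana tabacum
38	OsaTPS38	TPSc	826	544602148	Nicotiana tabacum
39	OsaTPS39	TPSc	821	544602148	Nicotiana tabacum
40	OsaTPS40	TPSe	812	62900385	Cucurbita maxima
41	OsaTPS41	TPSe	642	544602165	Nicotiana tabacum
42	OsaTPS42	TPSf	829	75163668	Arabidopsis thaliana
43	OsaTPS43	TPSg	426	75242446	Antirrhinum majus
44	OsaTPS44	TPSg	529	332319699	Fragaria x ananassa
45	OsaTPS45	TPSg	560	75224312	Ocimum basilicum
46	OsaTPS46	TPSg	467	75224312	Ocimum basilicum
47	OsaTPS47	TPSg	395	75251480	Ocimum basilicum
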