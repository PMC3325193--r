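species	genome_bp	at_pct	genes_pct	exons_pct	introns_pct	spacers_pct
Chara_vulgaris	67737	59.1	91	52	39	9
Marchantia_polymorpha	186609	57.6	51	23	28	49
Physcomitrella_patens	105340	59.4	65	37	28	35
Megaceros_aenigmaticus	184908	54.0	50	16	34	50
Huperzia_squarrosa	413530	55.8	27	10	17	73
Cycas_taitungensis	414903	53.1	20	9	11	80
Oryza_sativa	490520	56.1	14	8	6	86
Brassica_napus	221853	54.8	29	16	13	71
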