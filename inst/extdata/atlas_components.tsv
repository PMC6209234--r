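id	sub_atlas	component	anatomical_area
1	parietal	SPLA	Ventral intraparietal area (BA 7)
2	parietal	SPLB	BA 5
3	parietal	SPLC	Antero-medial intraparietal sulcus
4	parietal	SPLD	BA 7
5	parietal	SPLE	Posterior intraparietal sulcus
6	parietal	IPLA	Parietal operculum
7	parietal	IPLB	Anterior supramarginal gyrus
8	parietal	IPLC	Posterior supramarginal gyrus
9	parietal	IPLD	Anterior angular gyrus
10	parietal	IPLE	Posterior angular gyrus
11	TPJ	TPJa	Areas 39, 40, 22
12	TPJ	TPJp	Areas 39, 40, and 22
13	ventral_frontal	6v	BA 6
14	ventral_frontal	6r	BA 6
15	ventral_frontal	IFJ	Inferior frontal junction (BA 6, 9, 44)
16	ventral_frontal	44d	BA 44, dorsal
17	ventral_frontal	44v	BA 44, ventral
18	ventral_frontal	45A	BA 45
19	ventral_frontal	45	BA 45
20	ventral_frontal	47	BA 47
21	ventral_frontal	IFS	Inferior frontal sulcus (BA 9)
22	ventral_frontal	46	BA 46
23	ventral_frontal	FPl	Lateral frontopolar region (BA 10)
24	ventral_frontal	FPm	Medial frontopolar region (BA 10)
25	dorsal_frontal	Cluster1	Supplemental motor area (BA 6)
26	dorsal_frontal	Cluster2	Pre-supplemental motor area (BA 6)
27	dorsal_frontal	Cluster3	BA 9
28	dorsal_frontal	Cluster4	BA 10
29	dorsal_frontal	Cluster5	BA 9, 46
30	dorsal_frontal	Cluster6	BA 9, 46
31	dorsal_frontal	Cluster7	BA 46
32	dorsal_frontal	Cluster8	BA 8
33	dorsal_frontal	Cluster9	Anterior, dorsal premotor area (BA 6)
34	dorsal_frontal	Cluster10	BA 8
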