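pos	locus	aa	CS	M6	Vav1	Cc2	Cc1	Cc3	Cc4	RD	Sph1	M2	M3	M5	M4	M1	Com1	Com2	Splt1	Splt2	Splt3	Vav2
2903	Gene matK	A-G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	C	G	G	G	G
3400	Intergenic matK-trnK-UUU		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	A	A	A	A
4918	Intron rps16		T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	C	T
13015	Intergenic trnfM-CAT-trnT-GGT		T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	C	C	C	C
14580	Intergenic trnfM-CAT-trnT-GGT		C	C	C	C	C	C	C	C	G	C	C	C	C	C	C	C	C	C	C	C
15371	Intergenic trnY-GTA-trnD-GTC		A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	G	G	G	G
16481	Intergenic trnD-GTC-psbM		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
20853	Gene rpoB	Syn	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
25444	Gene rpoC2	Syn	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	A	A	A	A
32710	Intergenic atpH-atpF		C	C	C	C	C	C	C	C	T	C	C	C	C	C	C	C	C	C	C	C
44509	Intergenic ycf3 trnS-GGA		C	C	C	A	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C
45856	Intergenic rps4-trnT-TGT		A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	C	C	C	C
46434	Intergenic trnT-TGT trnF-GAA		G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	T	T	T	T
47628	Intergenic trnT-TGT-trnF-GAA		G	G	G	G	G	G	G	A	A	G	G	G	G	G	G	G	G	G	G	G
50332	Intergenic ndhC-trnM-CAT		G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	T	T	T	T
50716	Intergenic ndhC-trnM-CAT		T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	C	C	C	C
52295	Gene atpB	Q-K	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	T	T	T	T
56472	Intergenic rbcL-psaI		A	A	A	A	A	A	A	A	A	A	A	A	A	G	A	A	G	G	G	G
56670	Intergenic rbcL-psaI		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
63289	Gene petG	Syn	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	T	T	T	T
64318	Intergenic psaJ-rpl33		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
72207	Intergenic petB-petD		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
73742	Intergenic petD-rpoA		T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	C	C	C	C
78113	Intron rpl16		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
78732	Intergenic rpl16-rps3		G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	G	T	T	T	T
82499	Intergenic rpl23-trnI-CAT		T	T	T	T	T	T	T	T	T	T	T	T	T	T	G	T	T	T	T	T
100961	Gene rps15	Syn	T	T	T	T	T	T	T	T	T	T	T	T	T	G	T	T	T	T	T	T
102561	Gene ndhF	Syn	C	C	C	C	C	C	C	C	C	T	T	T	T	T	C	C	C	C	C	C
104993	Intergenic rpl32-trnL-TAG		A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	C	C	C	C
105477	Intergenic rpl32-trnL-TAG		C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	A	A	A	A
106672	Gene ccsA	Syn	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	C	T	T	T	T
113487	Gene ndhH	Syn	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	G
114943	Gene rps15	F-L	A	A	A	A	A	A	A	A	A	A	A	A	A	C	A	A	A	A	A	A
133405	Intergenic trnI-CAT-rpl23		A	A	A	A	A	A	A	A	A	A	A	A	A	A	C	A	A	A	A	A
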