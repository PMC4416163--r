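organism	annotation_class	g_old	f_old	a_old	g_new	f_new	a_new
Bos taurus	curated	734	3714	32232	2243	8421	144358
Danio rerio	curated	1807	2967	49834	3825	6848	179142
Drosophila melanogaster	curated	8722	6516	308962	10304	8850	517457
Bos taurus	computational	11646	6927	335063	5428	9107	232945
Danio rerio	computational	14114	3270	262940	15439	4191	345712
Drosophila melanogaster	computational	7950	2136	86207	8433	2560	96354
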