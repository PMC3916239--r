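# motif=HMG cutoff=6.6900000000000004
pos	A	C	G	T
1	-0.48542682717024171	0.89308479608348812	0.36257007938470837	-2.8073549220576042
2	-2.8073549220576042	1.8365012677171206	-2.8073549220576042	-2.8073549220576042
3	-2.8073549220576042	-2.8073549220576042	-2.8073549220576042	1.8365012677171206
4	-2.8073549220576042	-2.8073549220576042	-2.8073549220576042	1.8365012677171206
5	-2.8073549220576042	-2.8073549220576042	-2.8073549220576042	1.8365012677171206
6	-2.8073549220576042	-2.8073549220576042	1.8365012677171206	-2.8073549220576042
7	1.2801079191927351	-0.48542682717024171	-2.8073549220576042	-0.48542682717024171
8	-0.48542682717024171	-2.8073549220576042	-2.8073549220576042	1.5849625007211561
9	-2.8073549220576042	0.89308479608348812	0.89308479608348812	-2.8073549220576042
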