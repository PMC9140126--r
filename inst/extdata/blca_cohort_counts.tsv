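cohort	variable	level	count	printed_pct
discovery	stage	NAU	81	7.1
discovery	stage	Ta	229	20.2
discovery	stage	T1	262	23.1
discovery	stage	T2	371	32.7
discovery	stage	T3	146	12.9
discovery	stage	T4	46	4.0
discovery	sex	Female	135	11.9
discovery	sex	Male	459	40.5
discovery	sex	No_info	541	47.6
discovery	grade	G1	13	1.1
discovery	grade	G2	164	14.5
discovery	grade	G3	372	32.8
discovery	grade	Gx	13	1.1
discovery	grade	No_info	573	50.5
tcga	stage	T2	70	37.3
tcga	stage	T3	90	47.9
tcga	stage	T4	28	14.8
tcga	sex	Female	45	23.9
tcga	sex	Male	143	76.1
imvigor	response	Complete	11	8.3
imvigor	response	Partial	20	15.2
imvigor	response	Stable_disease	25	18.9
imvigor	response	Progressed_disease	76	57.6
imvigor	sex	Female	29	22.0
imvigor	sex	Male	103	78.0
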