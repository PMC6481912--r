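PMID	Sentence_ID	Entity1	Entity1OfficialSymbol	Entity2	Entity2OfficialSymbol	Negation	Voice	Verb	Re_Type	CELL	DRUG	DISEASE	ORGANISM	Origin
P001	1	Apoe	apoe	ins	ins	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P002	1	Apoe	apoe	ins	ins	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P003	1	Apoe	apoe	ins	ins	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P004	1	Apoe	apoe	c9orf72	c9orf72	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	frontotemporal dementia	NoData	verb_based
P005	1	Apoe	apoe	c9orf72	c9orf72	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	frontotemporal dementia	NoData	verb_based
P006	1	Apoe	apoe	c9orf72	c9orf72	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	frontotemporal dementia	NoData	verb_based
P007	1	Apoe	apoe	snca	snca	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	parkinson disease	NoData	verb_based
P008	1	Apoe	apoe	snca	snca	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	parkinson disease	NoData	verb_based
P009	1	Apoe	apoe	snca	snca	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	parkinson disease	NoData	verb_based
P010	1	Apoe	apoe	snca	snca	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	supranuclear palsy, progressive	NoData	verb_based
P011	1	Apoe	apoe	snca	snca	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	multiple system atrophy	NoData	verb_based
P012	1	Apoe	apoe	phgdh	phgdh	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	dementia	NoData	verb_based
P013	1	Apoe	apoe	phgdh	phgdh	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	dementia	NoData	verb_based
P014	1	Apoe	apoe	bche	bche	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P015	1	Apoe	apoe	bche	bche	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P016	1	Apoe	apoe	src	src	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	l-tyrosine	NoData	NoData	verb_based
P017	1	Apoe	apoe	src	src	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	l-tyrosine	NoData	NoData	verb_based
P018	1	Apoe	apoe	src	src	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	l-tyrosine	NoData	NoData	verb_based
P019	1	Apoe	apoe	mcidas	mcidas	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	dementia	NoData	verb_based
P101	1	ins	ins	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P102	1	c9orf72	c9orf72	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	frontotemporal dementia	NoData	verb_based
P103	1	snca	snca	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	parkinson disease	NoData	verb_based
P104	1	snca	snca	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	supranuclear palsy, progressive	NoData	verb_based
P105	1	snca	snca	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	multiple system atrophy	NoData	verb_based
P106	1	phgdh	phgdh	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	dementia	NoData	verb_based
P107	1	bche	bche	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	glucose	NoData	NoData	verb_based
P108	1	src	src	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	l-tyrosine	NoData	NoData	verb_based
P109	1	mcidas	mcidas	Mapt	mapt	POSITIVE	ACTIVE	associate	ASSOCIATION	NoData	NoData	dementia	NoData	verb_based
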