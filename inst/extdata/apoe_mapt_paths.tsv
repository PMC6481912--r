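EntityA	EntityB	EntityC	Similarity	AB_PMID	AB_Sentence_ID	AB_CELL	AB_DRUG	AB_DISEASE	AB_ORGANISM	BC_PMID	BC_Sentence_ID	BC_CELL	BC_DRUG	BC_DISEASE	BC_ORGANISM
Apoe	ins	Mapt	1	.	1	NoData	Glucose	NoData	NoData	.	1	NoData	Glucose	NoData	NoData
Apoe	c9orf72	Mapt	1	.	1	NoData	NoData	frontotemporal dementia	NoData	.	1	NoData	NoData	frontotemporal dementia	NoData
Apoe	snca	Mapt	1	.	1	NoData	NoData	parkinson disease	NoData	.	1	NoData	NoData	parkinson disease	NoData
Apoe	snca	Mapt	1	.	1	NoData	NoData	parkinson disease	NoData	.	1	NoData	NoData	parkinson disease	NoData
Apoe	phgdh	Mapt	1	.	1	NoData	NoData	Dementia	NoData	.	1	NoData	NoData	Dementia	NoData
Apoe	snca	Mapt	1	.	1	NoData	NoData	supranuclear palsy, progressive	NoData	.	1	NoData	NoData	supranuclear palsy, progressive	NoData
Apoe	c9orf72	Mapt	1	.	1	NoData	NoData	frontotemporal dementia	NoData	.	1	NoData	NoData	frontotemporal dementia	NoData
Apoe	snca	Mapt	1	.	1	NoData	NoData	parkinson disease	NoData	.	1	NoData	NoData	parkinson disease	NoData
Apoe	bche	Mapt	1	.	1	NoData	glucose	NoData	NoData	.	1	NoData	glucose	NoData	NoData
Apoe	c9orf72	Mapt	1	.	1	NoData	NoData	frontotemporal dementia	NoData	.	1	NoData	NoData	frontotemporal dementia	NoData
Apoe	src	Mapt	1	.	1	NoData	l-tyrosine	NoData	NoData	.	1	NoData	l-tyrosine	NoData	NoData
Apoe	phgdh	Mapt	1	.	1	NoData	NoData	dementia	NoData	.	1	NoData	NoData	dementia	NoData
Apoe	snca	Mapt	1	.	1	NoData	NoData	multiple system atrophy	NoData	.	1	NoData	NoData	multiple system atrophy	NoData
Apoe	src	Mapt	1	.	1	NoData	l-tyrosine	NoData	NoData	.	1	NoData	l-tyrosine	NoData	NoData
Apoe	ins	Mapt	1	.	1	NoData	glucose	NoData	NoData	.	1	NoData	glucose	NoData	NoData
Apoe	ins	Mapt	1	.	1	NoData	glucose	NoData	NoData	.	1	NoData	glucose	NoData	NoData
Apoe	src	Mapt	1	.	1	NoData	l-tyrosine	NoData	NoData	.	1	NoData	l-tyrosine	NoData	NoData
Apoe	bche	Mapt	1	.	1	NoData	Glucose	NoData	NoData	.	1	NoData	Glucose	NoData	NoData
Apoe	mcidas	Mapt	1	.	1	NoData	NoData	Dementia	NoData	.	1	NoData	NoData	dementia	NoData
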