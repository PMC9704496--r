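#count	freq	cdr3nt	cdr3aa	v	d	j
6	0.6	TGTGCCAGCAGTTTG	CASSL	TRBV05-01*01	TRBD01-01*01	TRBJ02-01*01
3	0.3	TGTGCCAGCAGC	CASS	TRBV07-02*01	TRBD02-01*01	TRBJ01-02*01
1	0.1	TGTAGCGGG	CSG	TRBV05-01*01	TRBD01-01*01	TRBJ02-03*01
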