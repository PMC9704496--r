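#count	freq	cdr3nt	cdr3aa	v	d	j
5	0.5	TGTGCCAGCAGTTTG	CASSL	TRBV05-01*01	TRBD01-01*01	TRBJ02-01*01
4	0.4	TGTGCCTGGACG	CAWT	TRBV09-01*01	TRBD01-01*01	TRBJ02-05*01
1	0.1	TGCACCAGC	CTS	TRBV11-03*01	TRBD02-01*01	TRBJ01-01*01
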