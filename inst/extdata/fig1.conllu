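# sent_id = fig1:s0
1	Activated	_	ADJ	_	_	2	amod	_	_
2	OxyR	_	PROPN	_	_	4	nsubj	_	_
3	then	_	ADV	_	_	4	advmod	_	_
4	induces	_	VERB	_	_	0	root	_	_
5	transcription	_	NOUN	_	_	4	obj	_	_
6	of	_	ADP	_	_	8	case	_	_
7	antioxidant	_	ADJ	_	_	8	amod	_	_
8	genes	_	NOUN	_	_	5	nmod	_	_
9	,	_	PUNCT	_	_	11	punct	_	_
10	including	_	VERB	_	_	11	case	_	_
11	katG	_	PROPN	_	_	8	nmod	_	_
12	,	_	PUNCT	_	_	13	punct	_	_
13	ahpCF	_	PROPN	_	_	11	conj	_	_
14	,	_	PUNCT	_	_	16	punct	_	_
15	and	_	CCONJ	_	_	16	cc	_	_
16	oxyS	_	PROPN	_	_	11	conj	_	_
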