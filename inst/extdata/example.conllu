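# newdoc id = essay01
# sent_id = essay01-1
1	Il	il	DET	_	_	2	det	_	_
2	governo	governo	NOUN	_	_	3	nsubj	_	_
3	nasconde	nascondere	VERB	_	_	0	root	_	_
4	la	la	DET	_	_	5	det	_	_
5	verità	verità	NOUN	_	_	3	obj	_	_
6	?	?	PUNCT	_	_	3	punct	_	_

# sent_id = essay01-2
1	Nessuno	nessuno	PRON	_	_	2	nsubj	_	_
2	controlla	controllare	VERB	_	_	0	root	_	_
3	il	il	DET	_	_	4	det	_	_
4	sito	sito	NOUN	_	_	2	obj	_	_
5	web	web	NOUN	_	_	4	compound	_	_
6	.	.	PUNCT	_	_	2	punct	_	_

# newdoc id = essay02
# sent_id = essay02-1
1	Mangiamo	mangiare	VERB	_	_	0	root	_	_
2	pizza	pizza	NOUN	_	_	1	obj	_	_
3	e	e	CCONJ	_	_	4	cc	_	_
4	pasta	pasta	NOUN	_	_	2	conj	_	_
5	.	.	PUNCT	_	_	1	punct	_	_
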