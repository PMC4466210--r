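breed	accession	pos_316	pos_342	pos_369	pos_420	pos_438	pos_459	pos_489	pos_528	pos_712
Large White	AF486874	C	T	T	T	G	G	C	T	C
Duroc	AY337045	C	C	C	C	A	A	A	T	T
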