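animal_id	group	role	breed_printed	pos_316	pos_342	pos_369	pos_420	pos_438	pos_459	pos_489	pos_528	pos_712
263-1	deceased	control	Large White	C	T	T	T	G	G	C	C	C
263-2	deceased	control	Large White	C	T	T	T	G	G	C	C	C
263-3	deceased	control	Large White	C	T	T	T	G	G	C	C	C
263-4	deceased	control	Large White	C	T	T	T	G	G	C	C	C
263-5	deceased	control	Large White	C	T	T	T	G	G	C	C	C
628-1	deceased	clone	Large White	C	T	T	T	G	G	C	C	C
629-1	deceased	clone	Large White	C	T	T	T	G	G	C	C	C
635-1	deceased	clone	Large White	C	T	T	T	G	G	C	C	C
635-2	deceased	clone	Duroc	C	C	C	C	A	A	A	T	T
637-1	deceased	clone	Large White	C	T	T	T	G	G	C	C	C
642-1	deceased	clone	Duroc	C	C	C	C	A	A	A	T	T
671-5	deceased	clone	Duroc	C	C	C	C	A	A	A	T	T
42-7	live	control	Duroc	C	C	C	C	A	A	A	T	T
42-8	live	control	Duroc	C	C	C	C	A	A	A	T	T
42-11	live	control	Duroc	C	C	C	C	A	A	A	T	T
42-12	live	control	Duroc	C	C	C	C	A	A	A	T	T
47-2	live	control	Duroc	C	C	C	C	A	A	A	T	T
43-1	live	clone	Large White	C	T	T	T	G	G	C	T	C
43-2	live	clone	Large White	C	T	T	T	G	G	C	T	C
43-3	live	clone	Large White	C	T	T	T	G	G	C	T	C
44-1	live	clone	Duroc	T2	C	C	C	A	A	A	T	T
45-1	live	clone	Large White	C	T	T	T	G	G	C	T	C
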