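kind	position	base	log_odds
donor	-3	A	0.4005
donor	-3	C	0.5656
donor	-3	G	-0.4739
donor	-3	T	-1.0589
donor	-2	A	1.263
donor	-2	C	-0.9434
donor	-2	G	-0.8365
donor	-2	T	-0.9434
donor	-1	A	-1.6439
donor	-1	C	-2.6439
donor	-1	G	1.696
donor	-1	T	-1.8365
donor	1	A	-7.9658
donor	1	C	-7.9658
donor	1	G	1.9957
donor	1	T	-7.9658
donor	2	A	-7.9658
donor	2	C	-4.3808
donor	2	G	-7.9658
donor	2	T	1.9797
donor	3	A	1
donor	3	C	-3.0589
donor	3	G	0.8156
donor	3	T	-3.0589
donor	4	A	1.5261
donor	4	C	-1.6439
donor	4	G	-1.1844
donor	4	T	-1.4739
donor	5	A	-2.0589
donor	5	C	-2.0589
donor	5	G	1.7312
donor	5	T	-2.3219
donor	6	A	-0.6439
donor	6	C	-0.5564
donor	6	G	-0.3219
donor	6	T	0.9107
acceptor	-20	A	-1.4739
acceptor	-20	C	0.3103
acceptor	-20	G	-1.4739
acceptor	-20	T	1.0286
acceptor	-19	A	-1.4739
acceptor	-19	C	0.3103
acceptor	-19	G	-1.4739
acceptor	-19	T	1.0286
acceptor	-18	A	-1.4739
acceptor	-18	C	0.3103
acceptor	-18	G	-1.4739
acceptor	-18	T	1.0286
acceptor	-17	A	-1.4739
acceptor	-17	C	0.3103
acceptor	-17	G	-1.4739
acceptor	-17	T	1.0286
acceptor	-16	A	-1.4739
acceptor	-16	C	0.3103
acceptor	-16	G	-1.4739
acceptor	-16	T	1.0286
acceptor	-15	A	-1.4739
acceptor	-15	C	0.3103
acceptor	-15	G	-1.4739
acceptor	-15	T	1.0286
acceptor	-14	A	-1.4739
acceptor	-14	C	0.3103
acceptor	-14	G	-1.4739
acceptor	-14	T	1.0286
acceptor	-13	A	-1.4739
acceptor	-13	C	0.3103
acceptor	-13	G	-1.4739
acceptor	-13	T	1.0286
acceptor	-12	A	-1.4739
acceptor	-12	C	0.3103
acceptor	-12	G	-1.4739
acceptor	-12	T	1.0286
acceptor	-11	A	-1.4739
acceptor	-11	C	0.3103
acceptor	-11	G	-1.4739
acceptor	-11	T	1.0286
acceptor	-10	A	-1.4739
acceptor	-10	C	0.3103
acceptor	-10	G	-1.4739
acceptor	-10	T	1.0286
acceptor	-9	A	-1.4739
acceptor	-9	C	0.3103
acceptor	-9	G	-1.4739
acceptor	-9	T	1.0286
acceptor	-8	A	-1.4739
acceptor	-8	C	0.3103
acceptor	-8	G	-1.4739
acceptor	-8	T	1.0286
acceptor	-7	A	-1.4739
acceptor	-7	C	0.3103
acceptor	-7	G	-1.4739
acceptor	-7	T	1.0286
acceptor	-6	A	-1.6439
acceptor	-6	C	0.4854
acceptor	-6	G	-1.8365
acceptor	-6	T	1
acceptor	-5	A	-1.8365
acceptor	-5	C	0.4854
acceptor	-5	G	-2.0589
acceptor	-5	T	1.0566
acceptor	-4	A	-0.1203
acceptor	-4	C	0.2141
acceptor	-4	G	-0.0589
acceptor	-4	T	-0.0589
acceptor	-3	A	-2.6439
acceptor	-3	C	1.3334
acceptor	-3	G	-4.6439
acceptor	-3	T	0.3561
acceptor	-2	A	1.9957
acceptor	-2	C	-7.9658
acceptor	-2	G	-7.9658
acceptor	-2	T	-7.9658
acceptor	-1	A	-7.9658
acceptor	-1	C	-7.9658
acceptor	-1	G	1.9957
acceptor	-1	T	-7.9658
acceptor	1	A	0
acceptor	1	C	-0.737
acceptor	1	G	1
acceptor	1	T	-1.3219
acceptor	2	A	0
acceptor	2	C	0
acceptor	2	G	0
acceptor	2	T	0
acceptor	3	A	0
acceptor	3	C	0
acceptor	3	G	0
acceptor	3	T	0
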