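id	variant	best_calc_ddg_kj_mol	md_ddg_kj_mol	experimental_ddg_kj_mol	esd_kj_mol
1	N65R	-5.4	17.3	2.1	na
2	N70G	-5.4	0.3	-0.6	na
3	S95R	-8.3	11.8	2.1	na
4	N96F	-13.0	-0.6	-0.2	na
5	N96W	-9.9	-6.1	-3.9	0.2
6	K115Y	-0.3	-9.6	0.7	na
7	T166M	-5.8	-5.4	2.0	na
8	T166Y	-9.8	0.9	2.5	na
9	H222R	-6.9	-15.8	-0.1	0.2
10	N96W + H222R	-7.1	-7.1	-5.0	0.2
11	N70G + S95R	-7.3	2.7	1.5	na
12	N70G + H222R	-4.6	-7.3	-0.3	na
13	S95R + H222R	-11.4	-10.8	1.5	na
14	N70G + S95R + H222R	-15.8	-5.6	0.5	0.1
15	Y66L	2.1	11.8	0.0	na
16	S71E	9.6	19.6	1.6	na
17	H222D	6.7	5.8	2.0	na
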