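group	n	region	snps	pi_x100	theta_w_x100	length_bp
all	32	all	1042719	0.32	0.39	65827877
rufipogon	10	all	855296	0.40	0.32	65827877
sativa	22	all	494458	0.24	0.19	65827877
indica	12	all	380807	0.21	0.14	65827877
japonica	10	all	230093	0.11	0.09	65827877
all	32	cds	256361	0.23	0.28	22536684
rufipogon	10	cds	210446	0.29	0.23	22536684
sativa	22	cds	122504	0.17	0.13	22536684
indica	12	cds	95410	0.15	0.10	22536684
japonica	10	cds	57316	0.08	0.06	22536684
all	32	noncds	786358	0.36	0.45	43291193
rufipogon	10	noncds	644850	0.46	0.37	43291193
sativa	22	noncds	371954	0.27	0.21	43291193
indica	12	noncds	285397	0.24	0.16	43291193
japonica	10	noncds	172777	0.12	0.10	43291193
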