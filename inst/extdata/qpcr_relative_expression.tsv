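rat_id	group	gene	m0	sem
A1	aggressive	Ascl3	0.16	0.02
A2	aggressive	Ascl3	0.88	0.30
A3	aggressive	Ascl3	0.82	0.08
A4	aggressive	Ascl3	0.09	0.04
A5	aggressive	Ascl3	0.18	0.03
A6	aggressive	Ascl3	0.07	0.07
A7	aggressive	Ascl3	0.27	0.11
A8	aggressive	Ascl3	0.32	0.05
T1	tame	Ascl3	4.85	4.38
T2	tame	Ascl3	3.40	1.69
T3	tame	Ascl3	1.75	0.24
T4	tame	Ascl3	2.21	0.12
T5	tame	Ascl3	2.92	0.05
T6	tame	Ascl3	4.48	0.17
T7	tame	Ascl3	3.83	0.33
T8	tame	Ascl3	2.64	0.15
A1	aggressive	Defb17	0.005	0.005
A2	aggressive	Defb17	0.01	0.005
A3	aggressive	Defb17	0.005	0.005
A4	aggressive	Defb17	0.005	0.005
A5	aggressive	Defb17	0.005	0.005
A6	aggressive	Defb17	ND	ND
A7	aggressive	Defb17	0.005	0.005
A8	aggressive	Defb17	0.005	0.005
T1	tame	Defb17	1.72	0.04
T2	tame	Defb17	3.22	0.42
T3	tame	Defb17	2.52	0.14
T4	tame	Defb17	1.82	0.55
T5	tame	Defb17	2.45	0.10
T6	tame	Defb17	4.43	0.26
T7	tame	Defb17	1.99	0.89
T8	tame	Defb17	2.34	0.27
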