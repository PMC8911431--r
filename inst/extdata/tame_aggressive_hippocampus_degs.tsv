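study_id	species	tissue	contrast	gene	log2	p	p_adj
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Alb	3.21	<10^-11	<10^-7
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Aqp1	5.91	<10^-6	<10^-2
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Ascl3	2.38	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Bag3	-0.92	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Baiap2l1	3.67	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Bdh1	0.40	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Cckbr	1.24	<10^-8	<10^-4
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Cspg4b	3.47	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Defb17	5.94	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Enpp2	2.41	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Frem1	3.16	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Gpd1	-1.34	<10^-6	<10^-3
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Hbb-b1	-6.19	<10^-7	<10^-4
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Hnf4a	6.51	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Htr2c	2.03	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Krt2	-1.43	<10^-6	<10^-3
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Lilrb3l	7.45	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Lypd1	-0.89	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Morn1	1.42	<10^-11	<10^-7
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Myom2	-1.24	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pcdhb9	-1.03	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pcdhga1	2.45	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pdyn	-0.89	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pla2g2d	2.84	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pla2g5	3.85	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Plod1	-0.67	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Ppp1r3b	2.45	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Prlr	6.43	<10^-5	<10^-2
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Pygl	-1.21	<10^-5	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Rbm3	0.89	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Retsat	-0.98	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Slc16a12	3.08	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Slc4a5	6.27	<10^-6	<10^-3
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Smoc2	-2.09	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Spint1	-1.39	<10^-7	<10^-4
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Sulf1	3.72	<10^-6	<10^-2
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Sync	1.17	<10^-3	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Tc2n	3.47	<10^-5	<10^-2
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Tecta	1.38	<10^-8	<10^-5
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Tmem60	0.79	<10^-4	<0.05
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Txnrd2	-0.71	<10^-5	<10^-2
tame_rat_hippocampus	rat	hippocampus	tame_vs_aggressive	Ucp2	0.73	<10^-4	<0.05
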