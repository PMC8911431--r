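study_id	species	tissue	contrast	gene	log2	p	p_adj
isiah_brainstem	rat	brain_stem	hypertensive_vs_normotensive	Hbb-b1	1.42	<10^-2	10^-2
isiah_hypothalamus	rat	hypothalamus	hypertensive_vs_normotensive	Hbb-b1	2.02	<10^-2	10^-2
isiah_renal_medulla	rat	renal_medulla	hypertensive_vs_normotensive	Hbb-b1	1.18	<10^-2	10^-2
isiah_adrenal	rat	adrenal_gland	hypertensive_vs_normotensive	Hbb-b1	1.32	<10^-2	10^-2
isiah_adrenal	rat	adrenal_gland	hypertensive_vs_normotensive	Hba2	0.69	<10^-2	10^-2
isiah_adrenal	rat	adrenal_gland	hypertensive_vs_normotensive	Hbb	2.02	<10^-2	10^-2
isiah_adrenal	rat	adrenal_gland	hypertensive_vs_normotensive	Hbb-m	3.78	<10^-2	10^-2
isiah_brainstem	rat	brain_stem	hypertensive_vs_normotensive	Hba2	0.58	<0.05	0.05
isiah_brainstem	rat	brain_stem	hypertensive_vs_normotensive	Hbb	1.88	<10^-2	10^-2
isiah_brainstem	rat	brain_stem	hypertensive_vs_normotensive	Hbb-m	3.65	<10^-2	10^-2
isiah_hypothalamus	rat	hypothalamus	hypertensive_vs_normotensive	Hba1	1.14	<10^-2	10^-2
isiah_hypothalamus	rat	hypothalamus	hypertensive_vs_normotensive	Hba2	1.32	<10^-2	10^-2
isiah_hypothalamus	rat	hypothalamus	hypertensive_vs_normotensive	Hbb	3.23	<10^-2	10^-2
isiah_hypothalamus	rat	hypothalamus	hypertensive_vs_normotensive	Hbb-m	1.09	<10^-2	10^-2
isiah_renal_medulla	rat	renal_medulla	hypertensive_vs_normotensive	Hbb	-0.68	<10^-2	10^-2
isiah_renal_medulla	rat	renal_medulla	hypertensive_vs_normotensive	Hbb-m	2.72	<10^-2	10^-2
isiah_renal_medulla	rat	renal_medulla	hypertensive_vs_normotensive	Hbb-s	2.38	<10^-2	10^-2
preeclampsia_placenta	human	placenta	hypertensive_vs_normotensive	HBD	-0.63	<10^-3	10^-3
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	HBD	-2.83	<10^-3	10^-3
pah_lung	human	lung	hypertensive_vs_normotensive	HBA1	2.08	<10^-9	10^-9
pah_lung	human	lung	hypertensive_vs_normotensive	HBB	2.46	<10^-10	10^-10
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	HBBP1	1.03	<0.05	0.05
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	HBE1	1.42	<0.05	0.05
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	HBG2	4.49	<0.05	0.05
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	HBM	5.33	<0.05	0.05
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	HBQ1	3.10	<0.05	0.05
ht_atrial_fibrillation_auricle	human	auricle_biopsy	hypertensive_vs_normotensive	HBA2	2.37	<10^-2	10^-2
isiah_brainstem	rat	brain_stem	hypertensive_vs_normotensive	Pcdhb7	1.60	<10^-2	10^-2
bph_bpn_kidney	mouse	kidney	hypertensive_vs_normotensive	Pcdhb16	1.22	<10^-3	10^-3
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB10	1.89	<10^-2	10^-2
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB15	1.47	<10^-4	10^-4
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB16	1.38	<10^-4	10^-4
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB17P	1.21	<10^-2	10^-2
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB4	2.93	<10^-4	10^-4
pulmonary_fibrosis_ph_lung	human	lung	hypertensive_vs_normotensive	PCDHB6	1.35	<10^-2	10^-2
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	PCDHB11	1.12	<0.05	0.05
ht_coronary_blood	human	peripheral_blood	hypertensive_vs_normotensive	PCDHB13	1.04	<0.05	0.05
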