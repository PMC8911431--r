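study_id	species	tissue	contrast	gene	log2	p	p_adj	family	domestic_lineage	wild_lineage
tame_rat_hippocampus	rat	hippocampus	domestic_vs_wild	Hbb-b1	-6.19	<0.05	<0.05	hemoglobin	tame_rat	aggressive_rat
tame_rat_hypothalamus	rat	hypothalamus	domestic_vs_wild	Hbb-b1	-3.97	<0.05	<0.05	hemoglobin	tame_rat	aggressive_rat
dog_wolf_blood	dog	blood	domestic_vs_wild	Hbbl	-5.92	<0.05	<0.05	hemoglobin	dog	wolf
dog_wolf_blood	dog	blood	domestic_vs_wild	Hba1	-4.06	<0.05	<0.05	hemoglobin	dog	wolf
chicken_pituitary	chicken	pituitary	domestic_vs_wild	Hbad	-1.07	<0.05	<0.05	hemoglobin	domestic_chicken	wild_chicken
dog_wolf_blood	dog	blood	domestic_vs_wild	Hbm	-6.46	<0.05	<0.05	hemoglobin	dog	wolf
dog_wolf_blood	dog	blood	domestic_vs_wild	Hbz1	-7.10	<0.05	<0.05	hemoglobin	dog	wolf
tame_rat_hippocampus	rat	hippocampus	domestic_vs_wild	Pcdhb9	-1.03	<0.05	<0.05	beta-protocadherin	tame_rat	aggressive_rat
tame_rat_hypothalamus	rat	hypothalamus	domestic_vs_wild	Pcdhb9	-1.01	<0.05	<0.05	beta-protocadherin	tame_rat	aggressive_rat
rabbit_cortex	rabbit	parietal_temporal_cortex	domestic_vs_wild	Pcdhb15	-1.04	<0.05	<0.05	beta-protocadherin	domestic_rabbit	wild_rabbit
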