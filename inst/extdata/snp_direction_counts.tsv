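scope	n_gene	n_snp	n_res	n_gt	n_lt	n_toht	n_fromht
genome_wide_tbp_sites	10000	100000	1000	200	800	NA	NA
hypertension_candidate_markers	3	85	27	8	19	8	19
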