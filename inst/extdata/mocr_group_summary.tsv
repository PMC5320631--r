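n_groups	n_tfs	groups_single_regulog	groups_two_regulogs	groups_three_plus_regulogs	max_regulogs_per_group	min_tfs_per_group	max_tfs_per_group
86	825	25	19	42	12	1	65
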