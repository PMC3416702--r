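quantity	value
combined_focal	1427
specific	725
preferential	702
matched_in_rice	471
matched_in_arabidopsis	140
matched_in_both	107
rice_dataset_size	548
arabidopsis_dataset_size	115
rice_subjects	213
arabidopsis_subjects	37
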