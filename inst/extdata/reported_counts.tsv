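quantity	value
expressed_flc	20859
expressed_alc	21195
universe_genes	21083
de_total	5753
flc_overexpressed	2357
alc_overexpressed	3396
not_significant	15330
splicing_events_total	1971
splicing_events_flc	1380
splicing_events_alc	591
spliced_genes_total	1437
spliced_genes_flc	1036
spliced_genes_alc	509
spliced_genes_both	31
ri_events_flc	742
ri_events_alc	34
de_with_splicing_flc	86
de_with_splicing_alc	56
flc_cells	151
alc_cells	148
enriched_flc	62
enriched_alc	120
specific_flc	9
specific_alc	50
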