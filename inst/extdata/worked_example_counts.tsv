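group	timepoint_min	label	count
mpk6_split	30	MPK6_dependent	180
mpk6_split	30	MPK6_independent	40
direction	30	induced_total	2114
direction	30	induced_dependent	262
direction	30	repressed_total	785
direction	30	repressed_dependent	85
direction	90	induced_total	2995
direction	90	induced_dependent	594
direction	90	repressed_total	2994
direction	90	repressed_dependent	508
cluster	30	cluster1	1136
cluster	30	cluster2	172
cluster	30	cluster3	197
cluster	30	cluster4	337
cluster	30	cluster5	242
cluster	30	cluster6	324
cluster	30	cluster7	1
cluster	30	cluster8	67
cluster	30	unassigned	72
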