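otu_id	Ice_1	Ice_2	Water_1	Water_2	Water_3	PC	DC
OTU_4	0	2	0	0	0	6088	8506
OTU_5	5	10	0	0	0	9522	3770
OTU_19	7	4	1	2	4	1174	2122
OTU_22	0	0	0	0	0	3169	0
OTU_25	2	0	14	46	57	2771	0
OTU_36	0	0	0	0	2	0	2165
OTU_63	0	0	0	0	0	310	1004
OTU_70	0	0	0	0	0	1170	0
OTU_98	0	0	0	0	2	0	728
OTU_103	0	0	0	0	0	0	141
OTU_167	0	0	0	0	0	269	0
OTU_209	0	0	0	0	0	12	0
OTU_1153	5	19	15	41	89	131	0
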