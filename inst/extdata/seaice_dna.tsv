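sample_id	dna_ng_per_ul	dispersion	below_detection
Ice_1	0.9	0.1	FALSE
Ice_2	0.4	0	FALSE
Water_1	0.9	0.1	FALSE
Water_2	1.1	0	FALSE
Water_3	0.1	0.1	FALSE
PC	NA	NA	TRUE
DC	NA	NA	TRUE
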