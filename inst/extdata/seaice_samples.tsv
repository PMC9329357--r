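sample_id	role	replicate_group
Ice_1	environmental_ice	ice
Ice_2	environmental_ice	ice
Water_1	environmental_water	water
Water_2	environmental_water	water
Water_3	environmental_water	water
PC	processing_control	processing_control
DC	extraction_control	extraction_control
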