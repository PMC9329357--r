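sample_group	cells_per_ml	dispersion
water	360000	40000
ice	34000	10000
processing_control	3000	NA
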