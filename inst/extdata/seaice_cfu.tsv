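sample_group	day	cfu_per_ml	dispersion	untrusted
water	5	40000	100	TRUE
water	10	3000	100	FALSE
water	15	5000	100	FALSE
water	20	2000	100	FALSE
water	25	3000	100	FALSE
water	30	1000	300	FALSE
ice	5	60	0	FALSE
ice	10	300	10	FALSE
ice	15	300	70	FALSE
ice	20	200	40	FALSE
ice	25	200	60	FALSE
ice	30	0	0	FALSE
processing_control	5	0	0	FALSE
processing_control	10	0	0	FALSE
processing_control	15	0	0	FALSE
processing_control	20	0	0	FALSE
processing_control	25	0	0	FALSE
processing_control	30	0	0	FALSE
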