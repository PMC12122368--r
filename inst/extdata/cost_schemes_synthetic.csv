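technique,low_usd_per_ha,median_usd_per_ha,high_usd_per_ha
coral_gardening,6000,28205,1800000
transplantation,9000,151000,4000000
artificial_reef,20000,1200000,143000000
larval_enhancement,12000,400000,60000000
intensive_substrate_addition,40000,2000000,261000000
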