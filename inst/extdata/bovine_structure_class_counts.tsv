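stratum	n_class1	n_class2	n_total
all	1827	1198	3131
species_specific	383	242	712
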