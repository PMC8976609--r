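status	n	carriers	non_carriers
breast	2400	285	2115
ovary	1697	332	1365
breast_and_ovary	32	16	16
breast_or_ovary_plus_other	33	1	32
other_site	116	5	111
cancer_free	3641	90	3551
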