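variable	count	total
dutch_mutation_carriers	19	517
men	225	517
psen1	368	517
app	106	517
women	292	517
psen2	43	517
apoe4_carriers	153	517
cdr_0	401	517
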