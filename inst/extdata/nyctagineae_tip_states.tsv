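taxon	state
Mirabilis	0
Commicarpus	0
Allionia	1
Cyphomeris	0
Anulocaulis	0
Nyctaginia	0
Okenia	1
Boerhavia	1
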