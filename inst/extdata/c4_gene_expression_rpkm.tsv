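species	pathway	PEPC1	PEPC2	PEPC3	NAD1	NAD2	NAD3	NADP1	NADP2	NADP3
Mirabilis jalapa	C3	164	19	105	50	28	4	122	4	75
Allionia incarnata	C4	12069	33	88	80	25	2001	1751	114	13
Boerhavia burburgiana	C4	17742	1	144	56	6	0.4	8563	2	144
Boerhavia coccinea	C4	9331	0.1	128	85	27	0.2	3562	2	121
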