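position	confidence_class	c4_grass_residues	c3_reference_residue	boerhavia_okenia	allionia	c3_nyctagineae
466	p>0.999	Ile, Val	Met	Met	Met	Met
517	p>0.999	Ala, Cys	Thr	Thr	Thr	Thr
531	p>0.999	Pro	Ala	Ala	Ala	Ala
560	p>0.999	Pro	Arg	Arg	Arg	Arg
572	p>0.99	Gln	Glu	Gln	Gln	Glu
577	p>0.999	Ser	Ser	Ser	Ser	Ser
579	p>0.999	Glu	Ala	Ala	Ala	Ala
599	p>0.99	Val	Ile	Ile	Ile	Ile
625	p>0.999	Ala	Val	Leu	Val	Val
637	p>0.999	Leu, Phe	Met	Met	Met	Met
665	p>0.95	Asn	His	His	His	His
733	p>0.95	Met, Val	Phe	Met	Phe	Phe
761	p>0.999	Ala	Ser	Ala	Ala	Ser
780	p>0.999	Ser	Ala	Ala	Ala	Ala
794	p>0.999	Val	Phe	Phe	Phe	Phe
807	p>0.999	Lys	Arg	Lys	Lys	Arg
813	p>0.99	Gln	Arg	Arg, Gln	Gln	Arg
863	p>0.95	Lys	Asn	Lys	Asn	Asn
866	p>0.95	Glu	Glu	Glu	Glu	Glu
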