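chemical_suffix	yl
chemical_suffix	oyl
chemical_suffix	one
chemical_suffix	one
chemical_suffix	ate
chemical_suffix	acid
chemical_suffix	ol
chemical_suffix	al
chemical_suffix	ane
chemical_suffix	ene
chemical_suffix	yne
chemical_suffix	ide
chemical_suffix	ine
chemical_suffix	amine
chemical_suffix	amide
chemical_suffix	oate
chemical_suffix	ium
chemical_suffix	ose
chemical_suffix	oxide
chemical_suffix	ile
alkane_stem	meth
alkane_stem	eth
alkane_stem	prop
alkane_stem	but
alkane_stem	pent
alkane_stem	hex
alkane_stem	hept
alkane_stem	oct
alkane_stem	non
alkane_stem	dec
alkane_stem	undec
alkane_stem	dodec
alkane_stem	tridec
alkane_stem	tetradec
alkane_stem	pentadec
alkane_stem	hexadec
alkane_stem	heptadec
alkane_stem	octadec
alkane_stem	nonadec
alkane_stem	eicos
alkane_stem	icos
alkane_stem	tetracos
trivial_ring	benzene
trivial_ring	pyridine
trivial_ring	toluene
trivial_ring	furan
trivial_ring	pyrrole
trivial_ring	thiophene
trivial_ring	imidazole
trivial_ring	pyrazole
trivial_ring	pyrimidine
trivial_ring	pyrazine
trivial_ring	indole
trivial_ring	quinoline
trivial_ring	purine
trivial_ring	naphthalene
trivial_ring	anthracene
trivial_ring	phenol
trivial_ring	aniline
trivial_ring	piperidine
trivial_ring	morpholine
trivial_ring	thiazole
trivial_ring	oxazole
simple_multiplier	mono
simple_multiplier	di
simple_multiplier	tri
simple_multiplier	tetra
simple_multiplier	penta
simple_multiplier	hexa
simple_multiplier	hepta
simple_multiplier	octa
simple_multiplier	nona
simple_multiplier	deca
simple_multiplier	bis
simple_multiplier	tris
simple_multiplier	tetrakis
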