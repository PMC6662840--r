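# KRT223 and KRT224 presence states for the species whose status is
# explicitly documented. KRT223: located 5' of Krt24 in the strepsirrhine
# primates (galago, sifaka) and the tree shrew; only a pseudogene remnant
# (KRT223P) in human; not documented for the other species -> UNKNOWN.
# KRT224: located 3' of Krt24 in the platypus and marsupials (Tasmanian
# devil) but not in the investigated placentals (human and other
# primates, tree shrew, cattle); a pseudogene remnant exists in human,
# the other placentals lack the gene -> ABSENT.
species	KRT223	KRT224
Ornithorhynchus_anatinus	UNKNOWN	INTACT
Sarcophilus_harrisii	UNKNOWN	INTACT
Bos_taurus	UNKNOWN	ABSENT
Tupaia_chinensis	INTACT	ABSENT
Otolemur_garnettii	INTACT	ABSENT
Propithecus_coquereli	INTACT	ABSENT
Homo_sapiens	PSEUDOGENE	PSEUDOGENE
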