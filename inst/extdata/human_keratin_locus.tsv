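# Human type I keratin cluster window on chromosome 17q21, bordered by
# the conserved anchors KRT222 and KRT12. KRT24 sits at one end of the
# cluster, flanked by KRT222 and KRT25; KRT25-KRT28 are the inner-root-
# sheath keratins, KRT10 the suprabasal epidermal keratin and KRT12 the
# corneal keratin. Coordinates are schematic (gene order and strand are
# the data of interest).
species	region	symbol	start	end	strand
Homo_sapiens	chr17	KRT222	1000	2999	+
Homo_sapiens	chr17	KRT24	11000	12999	+
Homo_sapiens	chr17	KRT25	21000	22999	+
Homo_sapiens	chr17	KRT26	31000	32999	+
Homo_sapiens	chr17	KRT27	41000	42999	+
Homo_sapiens	chr17	KRT28	51000	52999	+
Homo_sapiens	chr17	KRT10	61000	62999	+
Homo_sapiens	chr17	KRT12	71000	72999	+
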