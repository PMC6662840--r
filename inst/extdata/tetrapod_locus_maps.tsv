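# Schematic tetrapod gene maps of the keratin locus bordered by the
# conserved anchors Krt222 and Krt12 (coordinates schematic; gene order
# is the data). Documented configurations: human - KRT24 flanked by
# KRT222 and KRT25; alligator - a Krt24-like gene between Krt222 and
# Krt10; chicken - no Krt24 homolog in the window; platypus - three
# Krt24-like genes with Krt224 on their 3' side; galago (strepsirrhine)
# - Krt223 on the 5' side of Krt24; Tasmanian devil (marsupial) - Krt224
# on the 3' side of Krt24.
species	region	symbol	start	end	strand
Homo_sapiens	chr17	KRT222	1000	2999	+
Homo_sapiens	chr17	KRT24	11000	12999	+
Homo_sapiens	chr17	KRT25	21000	22999	+
Homo_sapiens	chr17	KRT26	31000	32999	+
Homo_sapiens	chr17	KRT27	41000	42999	+
Homo_sapiens	chr17	KRT28	51000	52999	+
Homo_sapiens	chr17	KRT10	61000	62999	+
Homo_sapiens	chr17	KRT12	71000	72999	+
Alligator_sinensis	scaffold_ki	Krt222	1000	2999	+
Alligator_sinensis	scaffold_ki	Krt24-like	11000	12999	+
Alligator_sinensis	scaffold_ki	Krt10	21000	22999	+
Alligator_sinensis	scaffold_ki	Krt12	31000	32999	+
Gallus_gallus	chr27	Krt222	1000	2999	+
Gallus_gallus	chr27	Krt10	11000	12999	+
Gallus_gallus	chr27	Krt12	21000	22999	+
Ornithorhynchus_anatinus	contig_k1	Krt222	1000	2999	+
Ornithorhynchus_anatinus	contig_k1	Krt24-like	11000	12999	+
Ornithorhynchus_anatinus	contig_k1	Krt24-like	21000	22999	+
Ornithorhynchus_anatinus	contig_k1	Krt24-like	31000	32999	+
Ornithorhynchus_anatinus	contig_k1	Krt224	41000	42999	+
Ornithorhynchus_anatinus	contig_k1	Krt10	51000	52999	+
Ornithorhynchus_anatinus	contig_k1	Krt12	61000	62999	+
Otolemur_garnettii	scaffold_og	Krt222	1000	2999	+
Otolemur_garnettii	scaffold_og	Krt223	11000	12999	+
Otolemur_garnettii	scaffold_og	Krt24	21000	22999	+
Otolemur_garnettii	scaffold_og	Krt25	31000	32999	+
Otolemur_garnettii	scaffold_og	Krt10	41000	42999	+
Otolemur_garnettii	scaffold_og	Krt12	51000	52999	+
Sarcophilus_harrisii	chr3	Krt222	1000	2999	+
Sarcophilus_harrisii	chr3	Krt24	11000	12999	+
Sarcophilus_harrisii	chr3	Krt224	21000	22999	+
Sarcophilus_harrisii	chr3	Krt10	31000	32999	+
Sarcophilus_harrisii	chr3	Krt12	41000	42999	+
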