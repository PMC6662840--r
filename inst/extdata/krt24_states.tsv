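# Functional-Krt24 states of the species whose status is explicitly
# documented: Krt24 inactivated in the genus Camelus (C. dromedarius,
# C. bactrianus, C. ferus) while intact in the alpaca; lost in cetaceans
# after their divergence from the hippopotamus lineage, with gene remnants
# (e.g. bottlenose dolphin) -> PSEUDOGENE; walrus, northern fur seal and
# California sea lion (clade Otaroidea) lack a functional gene, whereas
# earless seals (Phocidae) retain an intact one; intact in cattle, human,
# mouse and the blind mole rat.
species	KRT24
Camelus_dromedarius	PSEUDOGENE
Camelus_bactrianus	PSEUDOGENE
Camelus_ferus	PSEUDOGENE
Vicugna_pacos	INTACT
Bos_taurus	INTACT
Hippopotamus_amphibius	INTACT
Tursiops_truncatus	PSEUDOGENE
Physeter_catodon	PSEUDOGENE
Odobenus_rosmarus	PSEUDOGENE
Callorhinus_ursinus	PSEUDOGENE
Zalophus_californianus	PSEUDOGENE
Phocidae	INTACT
Homo_sapiens	INTACT
Mus_musculus	INTACT
Spalax_galili	INTACT
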