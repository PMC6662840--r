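# Rooted timed tree (branch lengths in MY, approximate divergence times for
# dating illustration only) of the mammals scored for functional Krt24:
# Camelus species and the alpaca, cattle, hippopotamus, two cetaceans
# (bottlenose dolphin, sperm whale), the Otaroidea (walrus, northern fur
# seal, California sea lion), the earless seals (Phocidae, one composite
# leaf), human, mouse and blind mole rat. Topology follows the documented
# clade relationships: Cetacea sister to the hippopotamus, Otaroidea =
# eared seals + walrus within the pinnipeds, Camelus sister to the alpaca.
(((((Camelus_dromedarius:2,(Camelus_bactrianus:1,Camelus_ferus:1):1)Camelus:15,Vicugna_pacos:17)Camelidae:47,(Bos_taurus:60,(Hippopotamus_amphibius:54,(Tursiops_truncatus:32,Physeter_catodon:32)Cetacea:22)Whippomorpha:6)Cetruminantia:4)Artiodactyla:14,((Odobenus_rosmarus:19,(Callorhinus_ursinus:9,Zalophus_californianus:9)Otariidae:10)Otaroidea:7,Phocidae:26)Pinnipedia:52)Laurasiatheria:18,(Homo_sapiens:90,(Mus_musculus:70,Spalax_galili:70)Muroidea:20)Euarchontoglires:6)Boreoeutheria;
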