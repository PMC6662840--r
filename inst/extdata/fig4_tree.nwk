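# Rooted timed tree (MY, approximate divergence times for dating
# illustration only) of the tetrapod/mammal species scored for the KRT223
# and KRT224 flanking genes: platypus, Tasmanian devil, cattle, tree
# shrew, galago, sifaka and human.
(Ornithorhynchus_anatinus:180,(Sarcophilus_harrisii:160,(Bos_taurus:96,(Tupaia_chinensis:82,(Homo_sapiens:74,(Otolemur_garnettii:59,Propithecus_coquereli:59)Strepsirrhini:15)Primates:8)Euarchontoglires:14)Placentalia:64)Theria:20)Mammalia;
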