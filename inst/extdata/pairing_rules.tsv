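# Default type I : type II keratin heterodimer pairing rules. K14 pairs
# with K5 (basal layer), K12 with K3 (suprabasal cornea), K10 with K1
# (suprabasal epidermis; K2 as fallback). K24 pairs primarily with K3,
# the main corneal type II keratin, but is a promiscuous partner and
# falls back to K4/K5 where K3 is missing (e.g. mouse cornea). Editable.
typeI	typeII	rank	promiscuous
K14	K5	1	FALSE
K12	K3	1	FALSE
K10	K1	1	FALSE
K10	K2	2	FALSE
K24	K3	1	TRUE
K24	K4	2	TRUE
K24	K5	3	TRUE
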