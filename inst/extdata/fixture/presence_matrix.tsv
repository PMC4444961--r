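mirna	Ixodes_scapularis	Acyrthosiphon_pisum	Tribolium_castaneum	Bombyx_mori	Drosophila_melanogaster	Aedes_aegypti	Athalia_rosae	Microplitis_demolitor	Nasonia_vitripennis	Nasonia_longicornis	Nasonia_giraulti	Apis_mellifera	Apis_dorsata	Apis_florea	Bombus_impatiens	Bombus_terrestris	Lasioglossum_albipes	Megachile_rotundata	Harpegnathos_saltator	Camponotus_floridanus	Atta_cephalotes	Solenopsis_invicta	Pogonomyrmex_barbatus	Polistes_dominula
ame-miR-281	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	0	1	1	1	1	1	1
ame-miR-306	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	0	0	1	1	1	1	1	0
ame-miR-279c	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	0	0	1	1	1	1	1	1
ame-miR-279d	1	1	1	1	0	0	0	0	0	0	0	1	1	1	1	1	0	0	1	1	1	1	1	1
ame-miR-6065	1	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	0	1	1	1	1	1	0
ame-miR-927b	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-980	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	0
ame-miR-2765	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	0
ame-miR-3786	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-6001	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-6048	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	1	1	1	1	1	1	1	1	0
ame-let-7	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-bantam	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-9a	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-71	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-124	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-184	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-275	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
ame-miR-276	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
dme-miR-2944a	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ame-miR-375	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0
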