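genome_id	insect_order	common_name	label	initial_panel
Ixodes_scapularis	Ixodida	Deer tick	solitary	0
Acyrthosiphon_pisum	Hemiptera	Pea aphid	solitary	0
Tribolium_castaneum	Coleoptera	Red flour beetle	solitary	0
Bombyx_mori	Lepidoptera	Silkworm	solitary	0
Drosophila_melanogaster	Diptera	Fruit fly	solitary	1
Aedes_aegypti	Diptera	Mosquito	solitary	0
Athalia_rosae	Hymenoptera	Turnip sawfly	solitary	0
Microplitis_demolitor	Hymenoptera	Parasitoid wasp	solitary	1
Nasonia_vitripennis	Hymenoptera	Parasitoid wasp	solitary	1
Nasonia_longicornis	Hymenoptera	Parasitoid wasp	solitary	0
Nasonia_giraulti	Hymenoptera	Parasitoid wasp	solitary	0
Apis_mellifera	Hymenoptera	Honey bee	eusocial	1
Apis_dorsata	Hymenoptera	Honey bee	eusocial	0
Apis_florea	Hymenoptera	Honey bee	eusocial	0
Bombus_impatiens	Hymenoptera	Bumble bee	eusocial	1
Bombus_terrestris	Hymenoptera	Bumble bee	eusocial	0
Lasioglossum_albipes	Hymenoptera	Sweat bee	facultative	0
Megachile_rotundata	Hymenoptera	Leafcutter bee	solitary	1
Harpegnathos_saltator	Hymenoptera	Jumping ant	eusocial	0
Camponotus_floridanus	Hymenoptera	Carpenter ant	eusocial	0
Atta_cephalotes	Hymenoptera	Leafcutter ant	eusocial	1
Solenopsis_invicta	Hymenoptera	Fire ant	eusocial	0
Pogonomyrmex_barbatus	Hymenoptera	Harvester ant	eusocial	0
Polistes_dominula	Hymenoptera	Paper wasp	eusocial	0
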