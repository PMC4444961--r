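mirna	genome_id	present	fact
ame-miR-2765	Apis_dorsata	1	h2_post_vespid_origin
ame-miR-2765	Apis_florea	1	h2_post_vespid_origin
ame-miR-2765	Apis_mellifera	1	h2_post_vespid_origin
ame-miR-2765	Athalia_rosae	0	h2_post_vespid_origin
ame-miR-2765	Atta_cephalotes	1	h2_post_vespid_origin
ame-miR-2765	Bombus_impatiens	1	h2_post_vespid_origin
ame-miR-2765	Bombus_terrestris	1	h2_post_vespid_origin
ame-miR-2765	Camponotus_floridanus	1	h2_post_vespid_origin
ame-miR-2765	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-2765	Harpegnathos_saltator	1	h2_post_vespid_origin
ame-miR-2765	Lasioglossum_albipes	1	h2_post_vespid_origin
ame-miR-2765	Megachile_rotundata	1	h2_post_vespid_origin
ame-miR-2765	Microplitis_demolitor	0	h2_post_vespid_origin
ame-miR-2765	Nasonia_giraulti	0	h2_post_vespid_origin
ame-miR-2765	Nasonia_longicornis	0	h2_post_vespid_origin
ame-miR-2765	Nasonia_vitripennis	0	h2_post_vespid_origin
ame-miR-2765	Pogonomyrmex_barbatus	1	h2_post_vespid_origin
ame-miR-2765	Polistes_dominula	0	h2_post_vespid_origin
ame-miR-2765	Solenopsis_invicta	1	h2_post_vespid_origin
ame-miR-279c	Apis_mellifera	1	fig3_eusocial_exclusive
ame-miR-279c	Atta_cephalotes	1	fig3_eusocial_exclusive
ame-miR-279c	Bombus_impatiens	1	fig3_eusocial_exclusive
ame-miR-279c	Drosophila_melanogaster	0	fig3_eusocial_exclusive
ame-miR-279c	Megachile_rotundata	0	fig3_eusocial_exclusive
ame-miR-279c	Microplitis_demolitor	0	fig3_eusocial_exclusive
ame-miR-279c	Nasonia_vitripennis	0	fig3_eusocial_exclusive
ame-miR-279d	Acyrthosiphon_pisum	1	h1_outgroup_conservation
ame-miR-279d	Aedes_aegypti	0	h1_lost_in_diptera
ame-miR-279d	Apis_mellifera	1	fig3_eusocial_exclusive
ame-miR-279d	Atta_cephalotes	1	fig3_eusocial_exclusive
ame-miR-279d	Bombus_impatiens	1	fig3_eusocial_exclusive
ame-miR-279d	Bombyx_mori	1	h1_outgroup_conservation
ame-miR-279d	Drosophila_melanogaster	0	fig3_eusocial_exclusive
ame-miR-279d	Ixodes_scapularis	1	h1_outgroup_conservation
ame-miR-279d	Megachile_rotundata	0	fig3_eusocial_exclusive
ame-miR-279d	Microplitis_demolitor	0	fig3_eusocial_exclusive
ame-miR-279d	Nasonia_vitripennis	0	fig3_eusocial_exclusive
ame-miR-279d	Tribolium_castaneum	1	h1_outgroup_conservation
ame-miR-281	Apis_mellifera	1	fig3_eusocial_exclusive
ame-miR-281	Atta_cephalotes	1	fig3_eusocial_exclusive
ame-miR-281	Bombus_impatiens	1	fig3_eusocial_exclusive
ame-miR-281	Drosophila_melanogaster	0	fig3_eusocial_exclusive
ame-miR-281	Lasioglossum_albipes	1	h1_albipes_presence
ame-miR-281	Megachile_rotundata	0	fig3_eusocial_exclusive
ame-miR-281	Microplitis_demolitor	0	fig3_eusocial_exclusive
ame-miR-281	Nasonia_vitripennis	0	fig3_eusocial_exclusive
ame-miR-306	Apis_mellifera	1	fig3_eusocial_exclusive
ame-miR-306	Atta_cephalotes	1	fig3_eusocial_exclusive
ame-miR-306	Bombus_impatiens	1	fig3_eusocial_exclusive
ame-miR-306	Drosophila_melanogaster	0	fig3_eusocial_exclusive
ame-miR-306	Megachile_rotundata	0	fig3_eusocial_exclusive
ame-miR-306	Microplitis_demolitor	0	fig3_eusocial_exclusive
ame-miR-306	Nasonia_vitripennis	0	fig3_eusocial_exclusive
ame-miR-306	Polistes_dominula	0	h1_polistes_loss
ame-miR-3786	Athalia_rosae	1	h2_sawfly_presence
ame-miR-3786	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-6001	Acyrthosiphon_pisum	0	h2_aculeata_universal
ame-miR-6001	Aedes_aegypti	0	h2_aculeata_universal
ame-miR-6001	Apis_dorsata	1	h2_aculeata_universal
ame-miR-6001	Apis_florea	1	h2_aculeata_universal
ame-miR-6001	Apis_mellifera	1	h2_aculeata_universal
ame-miR-6001	Athalia_rosae	0	h2_aculeata_universal
ame-miR-6001	Atta_cephalotes	1	h2_aculeata_universal
ame-miR-6001	Bombus_impatiens	1	h2_aculeata_universal
ame-miR-6001	Bombus_terrestris	1	h2_aculeata_universal
ame-miR-6001	Bombyx_mori	0	h2_aculeata_universal
ame-miR-6001	Camponotus_floridanus	1	h2_aculeata_universal
ame-miR-6001	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-6001	Harpegnathos_saltator	1	h2_aculeata_universal
ame-miR-6001	Ixodes_scapularis	0	h2_aculeata_universal
ame-miR-6001	Lasioglossum_albipes	1	h2_aculeata_universal
ame-miR-6001	Megachile_rotundata	1	h2_aculeata_universal
ame-miR-6001	Microplitis_demolitor	0	h2_aculeata_universal
ame-miR-6001	Nasonia_giraulti	0	h2_aculeata_universal
ame-miR-6001	Nasonia_longicornis	0	h2_aculeata_universal
ame-miR-6001	Nasonia_vitripennis	0	h2_aculeata_universal
ame-miR-6001	Pogonomyrmex_barbatus	1	h2_aculeata_universal
ame-miR-6001	Polistes_dominula	1	h2_aculeata_universal
ame-miR-6001	Solenopsis_invicta	1	h2_aculeata_universal
ame-miR-6001	Tribolium_castaneum	0	h2_aculeata_universal
ame-miR-6048	Apis_dorsata	1	h2_post_vespid_origin
ame-miR-6048	Apis_florea	1	h2_post_vespid_origin
ame-miR-6048	Apis_mellifera	1	h2_post_vespid_origin
ame-miR-6048	Athalia_rosae	0	h2_post_vespid_origin
ame-miR-6048	Atta_cephalotes	1	h2_post_vespid_origin
ame-miR-6048	Bombus_impatiens	1	h2_post_vespid_origin
ame-miR-6048	Bombus_terrestris	1	h2_post_vespid_origin
ame-miR-6048	Camponotus_floridanus	1	h2_post_vespid_origin
ame-miR-6048	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-6048	Harpegnathos_saltator	1	h2_post_vespid_origin
ame-miR-6048	Lasioglossum_albipes	1	h2_post_vespid_origin
ame-miR-6048	Megachile_rotundata	1	h2_post_vespid_origin
ame-miR-6048	Microplitis_demolitor	0	h2_post_vespid_origin
ame-miR-6048	Nasonia_giraulti	0	h2_post_vespid_origin
ame-miR-6048	Nasonia_longicornis	0	h2_post_vespid_origin
ame-miR-6048	Nasonia_vitripennis	0	h2_post_vespid_origin
ame-miR-6048	Pogonomyrmex_barbatus	1	h2_post_vespid_origin
ame-miR-6048	Polistes_dominula	0	h2_post_vespid_origin
ame-miR-6048	Solenopsis_invicta	1	h2_post_vespid_origin
ame-miR-6065	Apis_mellifera	1	fig3_eusocial_exclusive
ame-miR-6065	Atta_cephalotes	1	fig3_eusocial_exclusive
ame-miR-6065	Bombus_impatiens	1	fig3_eusocial_exclusive
ame-miR-6065	Drosophila_melanogaster	0	fig3_eusocial_exclusive
ame-miR-6065	Lasioglossum_albipes	1	h1_albipes_presence
ame-miR-6065	Megachile_rotundata	0	fig3_eusocial_exclusive
ame-miR-6065	Microplitis_demolitor	0	fig3_eusocial_exclusive
ame-miR-6065	Nasonia_vitripennis	0	fig3_eusocial_exclusive
ame-miR-6065	Polistes_dominula	0	h1_polistes_loss
ame-miR-927b	Athalia_rosae	1	h2_sawfly_presence
ame-miR-927b	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-980	Apis_dorsata	1	h2_post_vespid_origin
ame-miR-980	Apis_florea	1	h2_post_vespid_origin
ame-miR-980	Apis_mellifera	1	h2_post_vespid_origin
ame-miR-980	Athalia_rosae	0	h2_post_vespid_origin
ame-miR-980	Atta_cephalotes	1	h2_post_vespid_origin
ame-miR-980	Bombus_impatiens	1	h2_post_vespid_origin
ame-miR-980	Bombus_terrestris	1	h2_post_vespid_origin
ame-miR-980	Camponotus_floridanus	1	h2_post_vespid_origin
ame-miR-980	Drosophila_melanogaster	0	h2_initial_hym_specific
ame-miR-980	Harpegnathos_saltator	1	h2_post_vespid_origin
ame-miR-980	Lasioglossum_albipes	1	h2_post_vespid_origin
ame-miR-980	Megachile_rotundata	1	h2_post_vespid_origin
ame-miR-980	Microplitis_demolitor	0	h2_post_vespid_origin
ame-miR-980	Nasonia_giraulti	0	h2_post_vespid_origin
ame-miR-980	Nasonia_longicornis	0	h2_post_vespid_origin
ame-miR-980	Nasonia_vitripennis	0	h2_post_vespid_origin
ame-miR-980	Pogonomyrmex_barbatus	1	h2_post_vespid_origin
ame-miR-980	Polistes_dominula	0	h2_post_vespid_origin
ame-miR-980	Solenopsis_invicta	1	h2_post_vespid_origin
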