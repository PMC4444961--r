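clade	genome_id
Hymenoptera	Athalia_rosae
Hymenoptera	Microplitis_demolitor
Hymenoptera	Nasonia_vitripennis
Hymenoptera	Nasonia_longicornis
Hymenoptera	Nasonia_giraulti
Hymenoptera	Apis_mellifera
Hymenoptera	Apis_dorsata
Hymenoptera	Apis_florea
Hymenoptera	Bombus_impatiens
Hymenoptera	Bombus_terrestris
Hymenoptera	Lasioglossum_albipes
Hymenoptera	Megachile_rotundata
Hymenoptera	Harpegnathos_saltator
Hymenoptera	Camponotus_floridanus
Hymenoptera	Atta_cephalotes
Hymenoptera	Solenopsis_invicta
Hymenoptera	Pogonomyrmex_barbatus
Hymenoptera	Polistes_dominula
Aculeata	Apis_mellifera
Aculeata	Apis_dorsata
Aculeata	Apis_florea
Aculeata	Bombus_impatiens
Aculeata	Bombus_terrestris
Aculeata	Lasioglossum_albipes
Aculeata	Megachile_rotundata
Aculeata	Harpegnathos_saltator
Aculeata	Camponotus_floridanus
Aculeata	Atta_cephalotes
Aculeata	Solenopsis_invicta
Aculeata	Pogonomyrmex_barbatus
Aculeata	Polistes_dominula
Vespidae	Polistes_dominula
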