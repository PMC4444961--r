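(Ixodes_scapularis,(Acyrthosiphon_pisum,((Tribolium_castaneum,(Bombyx_mori,(Drosophila_melanogaster,Aedes_aegypti))),(Athalia_rosae,((Microplitis_demolitor,(Nasonia_vitripennis,(Nasonia_longicornis,Nasonia_giraulti))),(Polistes_dominula,((Harpegnathos_saltator,(Camponotus_floridanus,(Pogonomyrmex_barbatus,(Solenopsis_invicta,Atta_cephalotes)))),(Lasioglossum_albipes,(Megachile_rotundata,((Bombus_impatiens,Bombus_terrestris),(Apis_florea,(Apis_dorsata,Apis_mellifera))))))))))));
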