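taxon	group	origin	po_pct	fo_pct	mass_kg	lineage
Cattle (Bos taurus)	ungulate	domestic	1.32	3.85	167	Animalia;Chordata;Mammalia;Artiodactyla;Bovidae;Bos;Bos taurus
Bandicoot rat (Bandicota spp.)	rodent	wild	2.63	7.69	0.58	Animalia;Chordata;Mammalia;Rodentia;Muridae;Bandicota;
Giant pouched rat (Cricetomys spp.)	rodent	wild	3.95	11.54	1.25	Animalia;Chordata;Mammalia;Rodentia;Nesomyidae;Cricetomys;
Mouse (Mus spp.)	rodent	wild	21.05	61.54	0.5	Animalia;Chordata;Mammalia;Rodentia;Muridae;Mus;
Niviventer rat (Niviventer spp.)	rodent	wild	25.00	73.08	0.08	Animalia;Chordata;Mammalia;Rodentia;Muridae;Niviventer;
Rattus rat (Rattus spp.)	rodent	wild	21.05	61.54	0.15	Animalia;Chordata;Mammalia;Rodentia;Muridae;Rattus;
Giant flying squirrel (Petaurista spp.)	rodent	wild	2.63	7.69	1.65	Animalia;Chordata;Mammalia;Rodentia;Sciuridae;Petaurista;
Brown-toothed shrew (Episoriculus spp.)	shrew	wild	3.95	11.54	0.01	Animalia;Chordata;Mammalia;Eulipotyphla;Soricidae;Episoriculus;
Hill partridge (Arborophila torqueola)	bird	wild	1.32	3.85	0.31	Animalia;Chordata;Aves;Galliformes;Phasianidae;Arborophila;Arborophila torqueola
Wheatear (Oenanthe spp.)	bird	wild	1.32	3.85	0.02	Animalia;Chordata;Aves;Passeriformes;Muscicapidae;Oenanthe;
Puff-throated babbler (Pellorneum ruficeps)	bird	wild	1.32	3.85	0.03	Animalia;Chordata;Aves;Passeriformes;Pellorneidae;Pellorneum;Pellorneum ruficeps
Kalij pheasant (Lophura leucomelanos)	bird	wild	1.32	3.85	0.89	Animalia;Chordata;Aves;Galliformes;Phasianidae;Lophura;Lophura leucomelanos
Carp fish (Ptychidio spp.)	fish	wild	1.32	3.85	2.5	Animalia;Chordata;Actinopterygii;Cypriniformes;Cyprinidae;Ptychidio;
Snowtrout (Schizothorax spp.)	fish	wild	2.63	7.69	2.5	Animalia;Chordata;Actinopterygii;Cypriniformes;Cyprinidae;Schizothorax;
Barking deer (Muntiacus vaginalis)	ungulate	wild	9.21	26.92	18	Animalia;Chordata;Mammalia;Artiodactyla;Cervidae;Muntiacus;Muntiacus vaginalis
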