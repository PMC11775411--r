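taxon	group	origin	po_pct	fo_pct	mass_kg	lineage
Cattle (Bos taurus)	ungulate	domestic	24.32	45	167	Animalia;Chordata;Mammalia;Artiodactyla;Bovidae;Bos;Bos taurus
Goat (Capra hircus)	ungulate	domestic	8.11	15	26	Animalia;Chordata;Mammalia;Artiodactyla;Bovidae;Capra;Capra hircus
Sheep (Ovis aries)	ungulate	domestic	2.70	5	27	Animalia;Chordata;Mammalia;Artiodactyla;Bovidae;Ovis;Ovis aries
Dog (Canis lupus familiaris)	carnivore	domestic	2.70	5	12	Animalia;Chordata;Mammalia;Carnivora;Canidae;Canis;Canis lupus familiaris
Domestic fowl (Gallus gallus)	bird	domestic	13.51	25	0.78	Animalia;Chordata;Aves;Galliformes;Phasianidae;Gallus;Gallus gallus
Barking deer (Muntiacus vaginalis)	ungulate	wild	16.22	30	18	Animalia;Chordata;Mammalia;Artiodactyla;Cervidae;Muntiacus;Muntiacus vaginalis
Sambar deer (Rusa unicolor)	ungulate	wild	5.41	10	212	Animalia;Chordata;Mammalia;Artiodactyla;Cervidae;Rusa;Rusa unicolor
Wild boar (Sus scrofa)	ungulate	wild	2.70	5	38	Animalia;Chordata;Mammalia;Artiodactyla;Suidae;Sus;Sus scrofa
Rhesus macaque (Macaca mulatta)	primate	wild	2.70	5	6	Animalia;Chordata;Mammalia;Primates;Cercopithecidae;Macaca;Macaca mulatta
Eagle (Aquila spp.)	bird	wild	2.70	5	3	Animalia;Chordata;Aves;Accipitriformes;Accipitridae;Aquila;
Kalij pheasant (Lophura leucomelanos)	bird	wild	2.70	5	0.89	Animalia;Chordata;Aves;Galliformes;Phasianidae;Lophura;Lophura leucomelanos
Mouse (Mus spp.)	rodent	wild	13.51	25	0.5	Animalia;Chordata;Mammalia;Rodentia;Muridae;Mus;
Porcupine (Hystrix spp.)	rodent	wild	2.70	5	1.5	Animalia;Chordata;Mammalia;Rodentia;Hystricidae;Hystrix;
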