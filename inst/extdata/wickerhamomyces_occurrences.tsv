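# Global distribution and isolation sources of the 36 previously described
# Wickerhamomyces species (literature-compiled).
species	localities	source
Wickerhamomyces alni	Canada	Exudate of Alnus rubra
Wickerhamomyces anomalus	Algeria; Brazil; China; Colombia; Ethiopia; India; Iraq; King George Island; Lao; Russia; Slovakia; Sweden; Thailand	Beer and wine processing, phylloplane, soil, water, coral reefs, traditional alcoholic starters, mangrove forest, fermented food, flowers, fruits, fermented grains, coffee processing, wastewater treatment
Wickerhamomyces arborarius	Ecuador	Flower
Wickerhamomyces bisporus	Finland; France; USA	Platypus compositus, phoretic mites on Ips typographus, bark beetles (Dendroctonus)
Wickerhamomyces bovis	Portugal	Caecum of feral cattle (Bos taurus)
Wickerhamomyces canadensis	Canada	Beetle frass from Pinus resinosa
Wickerhamomyces chambardii	France	Chestnut
Wickerhamomyces chaumierensis	Guyana	Surface of flower
Wickerhamomyces ciferrii	Dominican Republic; USA; Thailand	Fruit of Dipteryx odorata, male olive fruit fly (Bactrocera oleae)
Wickerhamomyces edaphicus	India; Thailand	Forest and mangrove soils
Wickerhamomyces hampshirensis	USA	Frass of cut and dead Quercus, beetle (Xyloterinus politus)
Wickerhamomyces kurtzmanii	China	Crater lake water
Wickerhamomyces lynferdii	South Africa	Soil
Wickerhamomyces menglaensis	China	Rotting wood
Wickerhamomyces mori	China	Gut of wood-boring insect larvae on Morus alba
Wickerhamomyces mucosus	USA	Soil
Wickerhamomyces myanmarensis	Iran; Myanmar	Palm sugar in rum distillery, blood and central venous catheter of patients
Wickerhamomyces ochangensis	South Korea	Soil of potato field
Wickerhamomyces onychis	Brazil; Ethiopia; Iraq; Malaysia; Netherlands; Poland; Tunisia	Nail infection, fermented food, cocoa beans, spontaneous grape and tomato fermentation, soil
Wickerhamomyces orientalis	Iran; Sri Lanka	Fruits and rhizosphere soil
Wickerhamomyces patagonicus	Argentina	Sap exudate of Nothofagus dombeyi, glacier meltwater river
Wickerhamomyces pijperi	Egypt; Ghana; South Africa	Buttermilk, cocoa fermentation, orange juice
Wickerhamomyces psychrolipolyticus	Japan	Soil
Wickerhamomyces queroliae	Brazil	Larva of Anastrepha mucronata from fruit of Peritassa campestris
Wickerhamomyces rabaulensis	Ethiopia; Papua New Guinea; Thailand	Snail excreta, soils, decaying agricultural residues, decaying leaves and bark, fermented food
Wickerhamomyces scolytoplatypi	Japan	Gallery of Scolytoplatypus shogun in Fagus crenata
Wickerhamomyces siamensis	Thailand	Phylloplane of Saccharum officinarum
Wickerhamomyces silvicola	Germany; South Korea; USA	Flowers, gum of Prunus serotina, Prunus wood
Wickerhamomyces spegazzinii	Argentina	Fungus garden of an attine ant nest (Acromyrmex lundii)
Wickerhamomyces strasburgensis	France	Vegetable-tanned leather
Wickerhamomyces subpelliculosus	Egypt; USA	Fermenting cucumber brines, gut of honey bee, molasses
Wickerhamomyces sydowiorum	Brazil; Ivory Coast; South Africa; Thailand	Frass of Sinoxylon ruficorne in dead Combretum apiculatum, decayed plant leaf, fermented cocoa, honey, sand, water
Wickerhamomyces sylviae	Italy	Cloaca of migratory birds (Sylvia communis)
Wickerhamomyces tratensis	Thailand	Flower of mangrove apple (Sonneratia caseolaris)
Wickerhamomyces xylosicus	Thailand	Soil
Wickerhamomyces xylosivorus	Indonesia	Decayed wood
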