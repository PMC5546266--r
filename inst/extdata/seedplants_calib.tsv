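clade	taxon_a	taxon_b	min_age	max_age
Spermatophytes	Ginkgo	Quercus	308.14	365.63
Angiosperms	Amborella	Quercus	125.9	247.3
Eudicots-excl-Ceratophyllum	Nandina	Quercus	119.6
Rosids	Arabidopsis	Quercus	82.8	127.2
Vitales	Vitis	Leea	65.6
Cornales	Petalonyx	Cornus	85.8
Proteales	Nelumbo	Platanus	107.59
Monocots	Acorus	Musa	112.6
Chloranthales	Chloranthus	Hedyosmum	92.8
Austrobaileyales	Trimenia	Illicium	107.59
Cabombaceae	Cabomba	Nymphaea	111
Acrogymnospermae	Ginkgo	Pinus	308.14	365.7
Conifers	Pinus	Metasequoia	147	312.38
Gnetales	Gnetum	Welwitschia	119.6	312.38
Ginkgoales-Cycadales	Ginkgo	Cycas	264.7	365.63
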