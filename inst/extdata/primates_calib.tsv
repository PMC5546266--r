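clade	taxon_a	taxon_b	min_age	max_age
Scandentia-Primates	Tupaia	Human	61.5	130
Primates	Otolemur	Human	55.6
Haplorhini	Tarsius	Human	45
Anthropoidea	Callithrix	Human	33.7
Catarrhini	Macaca	Human	23.5	34
Hominidae	Pongo	Human	11.2	33.7
Gorilla-Pan/Human	Gorilla	Human	7.25
Homininae	Pan	Human	5.7	10
Lorisoidea	Otolemur	Microcebus	33.7	55.6
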