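taxon_id	domain	phylum	class	order	family	genus	pigA_T0	pigB_T0
OTU001	Bacteria	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	12	5
OTU002	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides	3	9
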