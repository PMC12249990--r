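name	formula	source
Methanethiol	CH4S	library
O-Methylhydroxylamine	CH5NO	library
Acetonitrile	C2H3N	library
Dimethyl sulfide	C2H6S	library
1,2-Butadiene	C4H6	library
Isobutene	C4H8	library
Methyl ethyl ketone	C4H8O	library
Isoprene	C5H8	library
Lactic acid	C3H6O3	library
N-Methylacetamide	C3H7NO	library
2-Butanethiol	C4H10S	library
Isopropyl acetate	C5H10O2	library
2-Ethoxyethyl acetate	C6H12O3	library
2-Nonenal	C9H16O	literature
Oxononanoic acid	C9H16O3	literature
Octene	C8H16	literature
Acetone	C3H6O	library
Ethanol	C2H6O	library
Acetaldehyde	C2H4O	library
Ammonia	H3N	library
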