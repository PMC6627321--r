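# Published uORF and mORF start-codon context windows for ABCA1 orthologs.
# Layout per window: up to 9 upstream bases + ATG + 9 downstream bases
# (left-clipped when the ATG sits near the transcript 5' end).
species	uorf_context	morf_context
Human	AAACAGTTAATGACCAGCCAC	TGAGGGAACATGGCTTGTTGG
Macaque	AAACAGTTAATGACCAGCCAC	TGAGGGAACATGGCTTGTTGG
Mouse lemur	AAGCAGTTAATGACCAGCCAC	TGAGGTGACATGGCTTGTTGG
Rabbit	AAGCAGTTAATGACCAGCCAC	TGAGGTAACATGGCCTGCTGG
Mouse	AAACAGTTAATGACCAGCCAC	TGTGGTGACATGGCTTGTTGG
Squirrel	AAACAGTTAATGACCAGCCAC	TGAGGTAACATGGCTTATTGG
Cat	AAACAGTTAATGACCAGCCAC	TGAGGAAACATGGCTTACTGG
Armadillo	AAACAGTTAATGACCAGCCAC	TGAGGTAACATGGCTTGCTGG
Tasmanian devil	TTAATGACCAGCCAC	TGAGGAAAGATGGCTTTTTGG
Opossum	AAGCAGTTAATGACCAGCCAC	TGAGGAGAGATGGCCTTTTGG
Platypus	TTCCAGTTAATGACCAGCCAC	TGAGGAAAGATGGCTTTTTGG
Chicken	CCGGAGTTAATGCCCAGCCAT	TGAAGAACGATGGCATTTTGG
Flycatcher	TTAATGCCTGGCCAC	TGAAGGAAGATGGCTTTCTGG
Anole lizard	GAGGAGTTGATGACCAGCCAC	AGAAGGAAGATGGCCTTCTGG
Coelacanth	AAAAAGTTAATGTCCGACAAC	TGGGAAAAGATGACTTTCTGG
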