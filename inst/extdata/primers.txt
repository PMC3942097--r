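# Degenerate screening primers (IUPAC), flat key=value format.
# The first pair anneals in the terminal regions and amplifies whole
# elements (and their internal-deletion MITE derivatives); the second pair
# covers a central portion of the transposase region.
BuT2_F=CAGTGCTGCCAACAWTTYGT
BuT2_R=CASTGCTGCCAATTTAGCYA
BuT2C_F=AGACYTCGGGRACAGTTTTGC
BuT2C_R=AGCATTAATGCYAARCTTTC
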