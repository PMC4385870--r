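# inline 8-base sample barcodes, min pairwise Hamming distance 3
AAATTACC
CGAGAACT
CCGCGGTG
TAGCTGGA
TGTCCTGA
AACCTAAG
AGCTGCTT
ATCGTCCG
GAGAAGCG
GCAACCCC
CATGAACA
CGTCATTG
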