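>BRAF_600
CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAGGTGATCGTCCCTGTCGATCG
AATTCGTTTCCTACCATCTGAAT
>EGFR_790
CTCTTAGATGTGCAAATGTTCACATAGACTCGTTATCTTACGCAGCAGGGCGTCCTAAATCTGCGTGAGCTCTACTACAT
CGGTAGTCGTCAGCCTCCACG
>EGFR_858
ATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTAGGCAATCTAACTCTTGTTGAGATATGTCAACCATCTA
AAGGGGAAAAGGCAAGAGGGGC
>EGFR_ex19
GCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCTTGCTCTAAGGAATTAAGAGAAGCAAC
ATCTCCGTTCGCAGCAAGAAAGGGAGGCCGAGAACGCAAGGCCTCTG
>KRAS_12_13
GCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACTATGACAATTTTATGGGGGAGTCAGAAGCCTCAC
GCTGGTATCTCAGACACATAAAGCA
>PIK3CA_1047
CCATAGGTGGAGAAATGGGTACGGACAAGGACGATGTCACCCTATTTGCAAACAGCGCTGAAGACTCCGAATGACCTTTT
TCAACTTTGTCCGCAATAATG
>PIK3CA_542_546
TAACCCACCTATTTTGCCCTGGCACATCAAGACGAACCGGTATAAAACAACATAAACGTTGAACCACTAGGCCCTGCTTC
ATTTAATCTTGCGGATTCCAAATCAAGGAGACG
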