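>synthetic_psat1_like_cds length=1113 note=synthetic stand-in CDS (seeded random sense codons), not the human PSAT1 sequence
ATGGTCGTTAATCAGGGCGTCTTGATATTCGTCTGGTCTGTTAAGAAGCCTGCAAAAGGA
GGGGACATTCCCAAGTGCATCCAACATTTAATTAGTCCTTGCACGCGTATGGTAGTACAG
ACTGCGGCATTCCAATGTACGCATGCCCCGACCAGTCTGCGCTCCACTGCGTCCCAGGTT
ACCAACGCCCGCAACAATGGCGCGTCTGGGCCTGGGAAAGGTCTTAGGAGAGCTGGAGTA
TATTTACAAAACTGGACCGTTCGGTTTGTCTGGATGTCCGTGACACACGAGGAGGACCGG
GTGCGCGTTAACCGCGGTTGTTACCGGGCTGGCCGAGGAAGACGGAACATACAGCGGGAG
ACCAGACGTGCACTTTATCTTACAGTTCAGTTACGATTATCGATTACTGAAGACATGGGG
ACTTGTATCCACTCAGGCTGCTCGACCCATTTATCGATTGACGCCGACCGTCCCTTGGTC
GACACTCCACATTGCAACACAACCACACGAAGTAGCGCAAGGACCCAAACCACGCTTTCG
GCCAGACATTTTATGCTACGCCTCTGCTGGGGGCGTACTCTTATCTGCGGCGATGGTAGA
GTGCTACCAGCAGGGTTAGGCGAACCCCTAACACGAAGCTCCGTAATGGGCCTCCGGCTT
ACGGCCAGTTGCACTGGGTTAACCCCTAATGAACGTGTTTCACTTGCAAGAGGTCCCCTG
CTGTGCGAGCGAATTGCGACGCAAAGGGCTTGCTGTCTGGTGGCATCCTTGCGCGCCGTC
ACATGTAAAAAAGTACCGCGGGCCGGGGCATTTGTAAGGCCTCTCGACACGAGCGCGAGA
ATAACGAGCAGCGTGGTCACTAGCTTTGGGGTCACGTCAGCTGGAACGATGGCATCGAGC
GCGAAAGCTCCACCTCGACTTGCAGGTCAATTATCACGAAAGCTCTCTCGCCTGTGCACC
GCTAAGGATAGGTTTGACAGTCATAACGGGCAAGACTCACGTATACGGAAACATGCTGTG
TTCTCAACAGGTCCAATGACCGGGAGCATCCCACAGCACTGCAACAGGGAGTCACGCACG
CACTACTTTCTCTTCAGTACCATAGAAAGTTAA
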