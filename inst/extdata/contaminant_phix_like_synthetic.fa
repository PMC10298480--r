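>phix_like_synthetic 1500 bp synthetic control-library stand-in
TATCCGTAATCCGTATGTGATGTCAATTCACGAATGCTTCCGCATGAAATGAGGGTTCGT
CCCCGTTGAAAAACTTGTAAAATTCCCTTATTCCCGGCGGAGATGTGGGAGAAGAAACCA
TGGTCAAGATCGTTCTGTGGGCTATGACTGTCAATATTTATACGGTACCTGGGGGTACGG
CACGCTGGAGGGAATAGTAGTTCTGACGACAAGGCACCCCACCGGATCGCCGATCCTGTA
AAACAAAGAGCTTCTATCACCCTCAAGGCGGGGGTGTAGGCCAGAAACATACTGGCTTAT
ATTTTATTTTGCCGTCCGCCCCCTCTCACCGGTCCCCCTTTTGGGATCTGAGAGTCTGAA
TACAACCCGAAGCGCGTTTTCGGGTCCCGCGGCCCGCGATTGCGCCCTACAGCATGGGTA
ACTAGTGTTGCCAATAGACCGCGCGCGGGGCGGTATAATTGTAGGATCCTCAGGCGGGGT
TGGTCTTAGCTGTACGCATGTGCGACAACCACCTAAGGACATCCTGGAACATGGGATGGC
GGTAAACAGCTTTGTAATTGCGTATTTCTCGCTCACACCAGCGTCCTACACTCACATGTG
GCGAAGCTATCGCATTCTCAGCAGCGTGGCTCCTTTTTCCAACCCGACAACCTCGCACCT
ATAACAGGCTCATGATGGTGTCTTGGCTACGTACTATGCTTAGTACTCTTTAAGAACGTA
GGCGTCTATTTTTAGATTCTGTCCTAATATGAGTGCTACACGGTAACTTAAAAAGTGGAA
GTTATGGCCCTTCCGATATTTACCATGCACGTGCCGCCGATAGGCGAGGTTTCGGTGGAG
TGTAATGTTGGGGCCTCGTACTCCCGAATCCCGATTGCGGTGACATGTTGACGCAGGGGT
GTAGTGCACCTCTTATTAAGAAGATACATAGGCCGGTCAAGGGAAACAGCAGCGAAACGC
CTACCTTCAACCGTCGCGTCTTACCGACTGGATAGGGGAAAGCGACAGTGCTCACGGGTT
CGTATCAGAGCACATAGTTCTCCCGATTCTGGCTCGCACGTACTGTTTGCTTAGAAGACG
GTCCGAACTGGAAGTGGCTCGAACGAACGTAGACGTGGCCGACGAGGTCCGGGTTGCTAG
AGAACGTGGTTTTTACTCCTCAACGCCAGGACGCATGAGATTGTGTAAAACAAGTCAATA
GACCCTGTCGCTCCGACACCGGCGTCTATACTAATCACCCCCTCCTGGAATCGATTTGCT
CTGTACGTACACTTTGATGATCTCTTCTAAAGGTGCGCGTAATGGGATTGTATGTGGGCG
TGACGAGGACAGGTTTGGACCCTCAACCGTGGCGAGGTGCGTCCATTTGTCACGTGTGTT
CGGAGATTCTTTGTTGAAGTTAAACCGGCGATTTAGCCGCTAATGTTGATCGGTGGCTAA
GACGTGTTTCATACTCCGGCTGAGATAAGAGCAGTCGCTGCATCGACAACACTTGACGCC
TATCCGTAATCCGTATGTGATGTCAATTCACGAATGCTTCCGCATGAAATGAGGGTTCGTCCCCGTTGAAAAACTTGTAAAATTCCCTTATTCCCGGCGGAGATGTGGGAGAAGAAACCATGGTCAAGATCGTTCTGTGGGCTATGACTGTCAATATTTATACGGTACCTGGGGGTACGGCACGCTGGAGGGAATAGTAGTTCTGACGACAAGGCACCCCACCGGATCGCCGATCCTGTAAAACAAAGAGCTTCTATCACCCTCAAGGCGGGGGTGTAGGCCAGAAACATACTGGCTTATATTTTATTTTGCCGTCCGCCCCCTCTCACCGGTCCCCCTTTTGGGATCTGAGAGTCTGAATACAACCCGAAGCGCGTTTTCGGGTCCCGCGGCCCGCGATTGCGCCCTACAGCATGGGTAACTAGTGTTGCCAATAGACCGCGCGCGGGGCGGTATAATTGTAGGATCCTCAGGCGGGGTTGGTCTTAGCTGTACGCATGTGCGACAACCACCTAAGGACATCCTGGAACATGGGATGGCGGTAAACAGCTTTGTAATTGCGTATTTCTCGCTCACACCAGCGTCCTACACTCACATGTGGCGAAGCTATCGCATTCTCAGCAGCGTGGCTCCTTTTTCCAACCCGACAACCTCGCACCTATAACAGGCTCATGATGGTGTCTTGGCTACGTACTATGCTTAGTACTCTTTAAGAACGTAGGCGTCTATTTTTAGATTCTGTCCTAATATGAGTGCTACACGGTAACTTAAAAAGTGGAAGTTATGGCCCTTCCGATATTTACCATGCACGTGCCGCCGATAGGCGAGGTTTCGGTGGAGTGTAATGTTGGGGCCTCGTACTCCCGAATCCCGATTGCGGTGACATGTTGACGCAGGGGTGTAGTGCACCTCTTATTAAGAAGATACATAGGCCGGTCAAGGGAAACAGCAGCGAAACGCCTACCTTCAACCGTCGCGTCTTACCGACTGGATAGGGGAAAGCGACAGTGCTCACGGGTTCGTATCAGAGCACATAGTTCTCCCGATTCTGGCTCGCACGTACTGTTTGCTTAGAAGACGGTCCGAACTGGAAGTGGCTCGAACGAACGTAGACGTGGCCGACGAGGTCCGGGTTGCTAGAGAACGTGGTTTTTACTCCTCAACGCCAGGACGCATGAGATTGTGTAAAACAAGTCAATAGACCCTGTCGCTCCGACACCGGCGTCTATACTAATCACCCCCTCCTGGAATCGATTTGCTCTGTACGTACACTTTGATGATCTCTTCTAAAGGTGCGCGTAATGGGATTGTATGTGGGCGTGACGAGGACAGGTTTGGACCCTCAACCGTGGCGAGGTGCGTCCATTTGTCACGTGTGTTCGGAGATTCTTTGTTGAAGTTAAACCGGCGATTTAGCCGCTAATGTTGATCGGTGGCTAAGACGTGTTTCATACTCCGGCTGAGATAAGAGCAGTCGCTGCATCGACAACACTTGACGCC
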