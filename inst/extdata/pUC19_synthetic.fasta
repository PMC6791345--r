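>pUC19_synthetic circular synthetic stand-in for pUC19 (L09137): anchor sites EcoRI@396 XbaI@423, primer sites 215F/774R; random elsewhere
GCCGGATGCTGGAGATGAACGACCCTTGCAAATAGGTTGTCAAGACATGCCCTAAGCTATATCCGAAATG
AGGTTGAAGGGATTAACCTGCTGCTTATTTGATAATCCAACTATGTGATGACGGTACAGGATGCCAGAAT
CTTATTCTATGGAGTCACAGTCGTCCCCGAAATATCAGCGAGAGGTCGCCACGAAGCGTAAATAGTGAAG
AACTAAGGAGAAAATACCGCATCAGGACTTTTATAAGCTTCATAATAAAGTTAGTGGATCGGTCGATGGC
AACCTGGAACGCTTAGGTAATATACGCTGGCGCTGAAGGCCGACTACATGTCTTATTTCGGCTTGGTTAC
CTGTTGTGGCGTGGGGTCACGCAACTCCCCAAATAGCCCCGGTCGAATTCTTCTAGTGCACCCATCAGTG
GTCTAGAGTCCGCTGGATTTCAGAGGTATCGAATGCAGACATGGGCGAGTAGTTATTACTTCCTGATTGC
GACTCCTCTCGGACTATCGATGCGACGTGACCCGGAGCCGTGTAGAGCACTCATCAGGTCTGATGGACTA
AGTGGGTTTCGCCCACGGGCGCTACCTACCAGGAAGGCTCGCGATAACGAGACCATACTTATTTTCATGG
TTCTGCGTCCCAGAGTGATATCCTATGCTGGTTGCCGGTAGACTGGACGCAGCTCAATACGGGGAAGCTA
TGATTTGTGTTAGGTGAAGACATGATTACTAACGAAGAGCCTCTTCCCATATCTCAAAGGCGGTAATACG
GTTACTTGTTTGGTTAATCGCTTAGGCTGTCTCTACCCGGCCCCTTGAAGCGATGGCGGGAACTGTCATT
ACCCCATGTCATCATACACCTCGCAGAACCTAATTTTTCCTATCAGGTACTGCCGTAGCCACTACAACGG
AAGAAGCTTTGTCAGTGGGAACGGGGCACGCAACGTTCACTCCCGCGTCACTAGACGTGCGTTTACATTC
GCTCGCCTCCCAACGATTGTGTCTATGTATTTATCATCCGTTGTGCAAGCCCTTCTTCGACTCGCCACAT
CCGTACTCTCCAACGTTAGTGTTTTCAGCAAGCCTGGCCCACAGCTCTGGGGACCGTATTCCGCTATTAC
TTTTGGGGTTCGTCAGGGTGCCGATCCTTGGCGACGGCAAGTTGATCATCATGACTGCCATGATTGCCCA
ATCCACGCCCTAGGACGTATTAATTACCCATGGTGGAAGCGCAAATGTCATACCCGGACAGATCGCAAGG
TACCTGTGCGCGCAGCCAACCAAGCCCATTCCAGTGCCATCAGACTGTTCACTCTGGAACAGCCAAGAAT
CTTTTGGGGCAGAGGTATACGGACTGGTCTGGTACACTCATTTCACACCTTGAGTAATGGCTACCCCTGC
AGTGTCGGAGAGAGAGTGAGTATCAAATGAAACCCACAACCCTATGGCCGGACTAAAGCTATATGGTCCC
CATATTACTACCCCGATTAGCCTCAGCCTCCGATGTAGCAATTTCCAAGTTCAAATGTTTCACGTGAGGA
ATGTGATTTGACAAAAGTCTCAGGGCGCGAACATAGACGTAGGTCTGGGTAGGCCGATTCTGGGACGATG
GGCAAAGTCAAGGCTGATGCCTCAGTTAAGCACACCTTAGACGTTCGAACCAGGCTAACACCCCAACGCG
TTCCCAACATACTCATTCTTAGGCACCTAGTTCTTCATCGGCACCCCGGACCTAAAGACTCGTACCTGGA
AATATCTACTACACAGCGTAACCATGGCAGTACTGTTCGAACTTGCCCGAACACAACCATTCCTGCTCGT
GGATGTTTGTAGCATGTGGCTAACAGATCGTAAAGGTGCGGACTCGTGAACAGCCGGACTCATCGTTGAA
TGCAAGGACGCCGGCAAAACACGGTGCAGACTCCTCATAAGGGACTAGGGAACTGGTGATTCGCCCCAAC
TGTGTAATCGTAACACTACGGTGACGGGCTACATCATCTACCTGTAAGGTCGGTCCATGTTTACCCCGGG
GACAAGCCGATATTACGGCTGAATGACAGTAGTGCATAGATTGTACATCTCTGAACGTAAGCTCGTGATA
ATCACGCATAGGCCCTATAAAAACAAAACAGCATACCGTTGATGATAACTCTGTTACATCACAAGAGTCG
CCGCATTAAAGGAGGGCTCGTGGCCTATGGACTCGCCTACCTCTTCCGACTTGTAACACTTTGTTTGCGT
TCTGGCTCTCGGCTACTTTGGTCGTCATGCAGCCCGTACCGAAGCTCAACGTGCCAAGTCTCGCGAACAA
ACCCCTAGTGACTGGAAAACCGGCCCCCACATGATTAATCCAGCTCTCATCTTCAGTTACAGTAGTTCCG
CTGTTGCGAATGCCTAAAAAATGAACTTCGTGGCCCGAACACACGTTTAAGAGTAGAACCTTCTAATTGA
AAGTGATGTTCTTAGCGATACCCGAAAATCCCGTTACTACATGCTGCAGCCCGGATTCAGGGATCGTCTT
CAGGAACAAAACACTCGAGATAGAGCACAGCTCTTCAGTAATATTATTTTTCATCCGGTTGAATCCATAG
AAATTACCTGAATGCCGGGAATGTTTCAGTGGCACGTGCCAGCATGTTCTACCGTCGGTCGGAAGAACCA
ACTTGGCTACTTCTGAATGTGCAGCT
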