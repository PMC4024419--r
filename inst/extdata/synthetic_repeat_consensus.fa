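>ALUSYN synthetic repeat consensus (seeded random; not a biological sequence)
CTGCGCAACATGAAGCAGAGGATACCGACTTCGCCGACTGAGCGATGTCGTTAACAGTCC
CTCACGCGGCTAATGCCCAGCAGAGAAGCTTTCAGAATGGGATAAAGTTACGAGCAGGTT
CGCCAAAGTATCTTAGTAAGCTCATTCTCAAAATTTGCACAAGTGCTCCCCATTGATAAT
GAGTCCAAATGGACTCTCACTACGTGTTTCGCACGTACGCTACATTTTCCCGCCTGGCCG
AGCTTGGGTGACTATTGAGAGAAGTTATTTTTAAGACTTGGAGAAGCGGGGTTACCAGAC
ACAACCCTAG
>L1SYN synthetic repeat consensus (seeded random; not a biological sequence)
GGGTGTAGTGACATTCTTAGTTGCCAGAAGGGCTACAAAAGAGCCTTAAGTCACAGGCTT
TATTCGCATACAACTACCAAGAGATGGAGTCCAAGACCTTCAGGTTCGTTAGTTTGGAGC
AGTTAGAATGATGCGTTACTGATGATGTCGCTAGGCAGTGACGTGGGGCAAGTCGGTGTG
CTTCAGTCGAGAAGAAGGACAACGACCGCTGAGCCGTATGATTGGACACGTTAGTTCACA
GTCGGCTTCGGAAAGTAAGGTTGAGCACAGTGCATATCTCCGTGACCCCGAGACCAAGGA
TTCCCGGTAAAGTCACATTGAATGCGCATGCTGATTGATAGCATGTACCGTCGCATGGTG
TACGCTGTAATAAGGGAGTCGTCCTGGAGTCTCGACCCATTCGGGTTCATACGCGCAGAG
CTATGAGTTAATGCGATGAGACCAAGTTGGTCGTGGGCAGAACGTTGGCTCCACTGTACG
GGTAACCCGAGGACATTAGTACCTATGGCGAATCGTGTGTTCGGTGAAGTACTAAAGAAC
AAGGGAGGATCTAATTAAGTCCTTTACGTAAGAAGTGCACTTAAGTAATTAGACATATAT
GTGCAAAATGTATTGGCGTACGTGTGTGACCCGCTGACCGGACCGTAGCCGTGCACCACC
ATGATTGAGATTCGTCCTGGAGATGGAATTAAAACAAGAGCCCAAGGGGGTATATCGGGG
AAACGATAGTAGCCCAATGGGCCAACAGCTCTCCCCTTAGCTTCATAGATTTAGACTAGT
GACAGGGCAAGCGCAGGCCGCCCAAACAACTACTCGCGAGAAGATCAAGGGGATGGTACG
CCCTGTAGCGGCCCGGAATAGCACGATTGAACTACCTGAGTCAATTGGCTTAATTCTACG
TTAAGTGGACTGCCACCAATCGCAACCCGTGTCAGGTTATCAGCCTAGCTTTAACCGTTG
GACTACAAGGCTACATAGGGAGGGTGGTCCAGATTCGGCC
>L2SYN synthetic repeat consensus (seeded random; not a biological sequence)
AGATCATCGGCTGGCTATGCCGTCAGAAAAAGTCTATAAGGCCCGCGGGTGAGATCCATA
TGCTGTTTGGGGACTAGAGGGGATACCTTCATACTAACTCCTGTAGTTCAACCGTGTTTT
GTTCTGCATGTGTTTGTCCCAGCTATCCCTTTGTACATGATACTAAGATTTCCAGCATGG
TGCGACCTAGCAGCAGCATCGAATTAGTCAATATTAATCTGCCTAGGTACCCGTTCGAGG
GGAGTGTTAACACGCCAGTTTCCCATTACTCATGCCCTTACACGTGTTTTTTAGTAAAAT
GTGCTTCCTATTGCGTCTCGTTCAATAGTGACAACTTAGAGATTTTTATTTCAGCGGTAT
GGTCGGCTTGAGTGAATGAACCAGCTTACTTAGCCGAGACGAGCATCTTGTAGCGATATG
GTCGCGACGCCGAAATAGGAAACATGGACGCGTTTCGTCCTCATTGGGCCATTAACTATG
GGGCTTCATCCCACCAGCTTGGAACTCAGGTTGTCTTGGGAATTCACTGAACAAACACAG
GGGCTCTAGCAGTTCTTATACCCTCTGGACCCGTGTTAAGCCCACCTCTTGTCCTCCACA
>MERSYN synthetic repeat consensus (seeded random; not a biological sequence)
GATTCATCTCCAGGCGATCCACGTTATACATGACTTCTGACCACGTCATTGTATCTAGAG
TCCCGGAGCCCCGGATTGGATTCATATTTCGCGACAAGTGAGAAATCGTTGGGTAATACA
TTCCGTTTACATAGGGCGGGTACGTCCCTCGCGTAAATTAACCACAGAGCTACGGGAGGC
AAGACCGCCGCCCGAGTTTA
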