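>pBR322_synthetic topology=circular
TTGCCAAAAAAGTAAAGGTCATTTCTTCATCAATGTATTGCGCGGTTCATATTTCCTCGTCGCTGTCGTC
TCGACTACTCGGCCTTAGTGGAATACATCCTTGGCTATCTGCTTGGCGTCGACTATCCTAGATAAGAACG
TAATCGGTTTGACGGCGCTTACACCGCCCAAGGTGTTCCCCTGGGGTCCTACTAACTGCCGTCGTGTCCG
CCTTGAGTTGTTTGGCGACACGTTGGTTGCACGACGAAGGAAGCCCAATGACGTGAGAGGTAATCACGAA
ATTCGCAAGGGCGAAGAACAGGCATCCTAGACTGCGCTTAAGCACGTGCCGTAATGGATGGCTATCGTAG
AACCCGCCACTGTAGGTAACGCCTCGATCACTAACGGGTTTGTTCAATAATGAAATCAAAGTCTCCCCCT
TCATGGACCTGGACCATTCCAAATGGTTCCACTCGCGGACCCAATATGATTTTCATATTGTTCCTTACGG
CGAACGGGCCATCGCTAATTAGTGAATGTCGCGGTCGCCCTGCCGGACGGGAATGTCAGGAGGTTGTATG
TATGTTTAAGCCTTTATATCTCGCCAGTGGGGCAGGCGACGGCCCCTGTGATCGATTTGTCAGTCAATCA
GCACAAACCTTACGTCGAGTGAACTTTAAAGTGAGCAACGATATACACCACTAGGCTGTTGACTTGCTTT
GTGCTCATTGCCTCATGGTCTGACTTAAGTTTTTCAACCCTCTTATTAGCCAAACAACCAAGGTAACTTT
AACCACCACTCACCAGCTATAGTGTGTTTACATCCCATACTCTCCTGAAGTCCCTGCCGTGTGGACTCGA
AAGTAATACCGAGACTCATACTGGCCTCTGTACTATGCGTAAACATACAATTTACAACAGCCTTGTTTAA
CCATGAATGTGGGATCAATGGGAGTCTCACGGCAAGGGTGTCCATTGTACGAGGCTCCCGCTCGCGACGC
GAGGCTGGATGGCCTTGCCTGACGGAGGGCTCGATGTGGACCAGAGGTAAAACACTTGGTTCCAATTCGT
TCTGCGAAGTGGCGATTCCTCAGGCCGTGCGAGCGACATAACGGTTAGAGAAATTCCTCTTTGTCTGCAC
GAAATGATAATATCTTCCGTTCCCTACATATTGGGTCGAAACGAGGTCTGCATGATACTAGAACTCTAAG
CACGGGATTCCATATATCACTGATCTCTAGCGCCTTTCCCACTAAGTCCCTCTGGGTTGGTAGGTGAGGA
GGCTACTCATCTGAGTTATGAAGGGGGAGGCCGTCACTTTAATACGGTAACCTAGAAATCGCTTCTGGAT
GCATCCTTGTCTTGGAGACGCCTTAACATGTATACCTACCCACGACAAATGCCTTAGCTACGAAAACTCA
AACGAGTGCCCTGTACATAACTGGACAGGGGGCTTAAGTGAAGATGGGCGTGTGGTACAAACGAACTGCA
GGCCTAAGTCCGCTCGCGTTATGAGGAAGCGGATGTCTACGCGGTCATAAGACAAGATGGGGTCTCTCAG
TCTATCACCTTATGACTCCAGATAACTGCCTGGTTACACTCCAAGAGCCCGATCTACGTTCGTTCCTTGT
AGCATCGGGCACACATGCTCAGACTACGCGTTGATTCGCAGATTGAAGTAGGAAAAACCTTTTTTTGCCG
TTTGTTCTATCGGAAGCCTCGTATCCGGGAGGGACCTCAGTCGTTCTTTAATTTGTAATTGACAAGGGTT
CGTATAAACGCGTCACTAGTGATCGCGTACGACCTTGGTGATGTTATGCGGATCGCATCCTCCCATACAA
CCCTGGGTCCCATTTGTCGTACCTCAAGATATATCCACACGACCTCGCGCTACCGAAATCTGCGTCGACG
CTGCTCTATACGGAACGATCACCAATCAGAAACTATGTCACTCTCAAGATTGAAGGGGAGAGTCAGGGGT
TCACGTATTCATAATTCACTGAACACACACTGAACTCCATGGTTGCAGATACCAAAAGGGTCTCAATAAC
AATTGTGCGCTGGAGACGATTGATGCTAGCGAATGCCTCCTACTGACGATCGGCTTTTACCGATAAAGGT
CGTGCATAGTGTACTGATGATTCCTCGTGTACATCAATAAGTTGATGGGCACCCCGCCGATTCCGATTTT
ATGTTGTCTGTCTGTCTAATTGCGCTTTAAACTCGTTTATGTTAGCCGAAGTATCTGACTCCGACTGCGC
CTAATCACCTCTCAAATGACTAGGAAGCCTCATGTTGTCTCCACTATCTACGATCTAACCGCGCCGTCCG
AGGGGATAGCAGTGCCCAATTGTCGCCCTTTTTGTGCACTATATCCGAGCTGAGGGTCTGTCCTGCTTAG
ATAGGGCAGTGAAGGTAGGGCGGTGGCGCCTGAGCTGCAAGCACATGACGGAGTCGTCCCATCCTCTGAA
CGGCTGTCGGTAAAGCAGGCATCATAAGCTGCCTGGCGGCGCTAGTATTGTCCACCAGAGGGGATGCATA
ACACGCTCCTATGGATAGGTATGTACACAACGACGTTCGCATGATGGGAGACAAAACAGGCGTACACCTG
TTGGTAGCCCCGACCCATAGACCTAACTTTGTGCAAGCAGCATGTTTTAATTCCAGCTAACTCAACGCCT
AGGCATGCATACCGCCACCGGGAGACCTCCGGGTCGTGAAGTAGACCGGCCTGCGCTTCCCTTGGTTATA
TATAATTTGAATGAGTCTCTCGCCTAGTCCTACTTAGTGCTGGTGAGAAAGCCATTAGACCAGCTCGATC
ACTGTCGGAGACCGCTGAAGCTCACGTCTGTATCTAACGAGCACATTGATCGAGGACGGTCCCTGCATGG
TCGACTATATTGGGCATAGTTTGTTGTCTGGCTACGAAGTCCGGTCTGAAGGAAAGACCACTAGGTCTTC
ATGATGTGCTCTACGCCACCCCTAGGCCTCCCACCCACGAGGATGCAACTGAGTGTCTTTACCGTGACCA
TATTTATATGTTGGTGGCTAACTTTTATAACGCAGATCTCAACCGGGCGAGTTGCGGGACACTATCCCCC
TGTTTAGTACCCAGTTTGAAACTAGTCAAACCATAGATTCTAGCAAACGGCTCAGCATATGTTCTGAGAG
TCCGCGCGTGAACCATGGCTCCGCCAGATTAGTGTCACACTCACGCCTACACATCTTCAGGGCGCTTCGG
ACACAGGGGTAAGTCCCGAGATTGGCCACTGCTCCCGAGCAAACAGTGGTGACCCTGACGGCTTTCCTCT
TTTTGACGTCGGCCATAAGGTACGTACATCTGATTGAAGAACTCGGCAATATGTCATCGGCCTCATCTGA
AGGGCCCCCGTCACTCGGAATATCTTACACGATGTTGTGGGCTCGCTAATCTTCCCCAGGTTGACTCTGA
ATCGCTAGTTCGCTGGGAATATACTGGGCCGGGGTCACTAGAAGCGTTTACCAGTACTGCTGCTCACCGT
ATGTCGAATACCTTAAGAGCGGACTTGCATGAGGAAATAGCGCGGACCCGAATCTCCGGGGGTCATGCAA
CCCTACTAGGTTAGGCATCACTTTATCCTTACGATAGTCTTCCCACCAGTAGAAGAATCCACTAAGAATA
GCCCGGTATCCGCCGTGTAGCTCATCTACAAGTTGGAATAACGCTGTGCGCGAGAATCAGACCGTGGTTT
GCATTCCACTCACGGTCACATCGCAATATTTGAGACTTACCGTCGTGAGCGGACGCAATTATAGCTATTA
GGAATGGTTAGAGCAATCGCGGGGTGCCCAATGACCGGATATGATCACATTCCTGTAGTGGTGCTAGAGG
ATCTTAAAGGACGATAAGCGAGTCCGCAGAGACCATTAATGTGCGGGAAATCTGGTGGGCTATAGTCCTA
CTGGTAAGAAGTACCTGTTACCCTGTGTTCACCCCCTATTACAGGGGCCAGCCATAATGGCAACTGCAGT
CTAACCACGAAGATCATGAAGGGGTCCTTAGACCAAATACGACGTGAAGTGAGTTCTGTGGAATCTTGCA
ACTTATATAACCCCAACTTATCTGACTCTTATTTCCAGGAATCTAAGGTTCTCACTACCCCTATCAGACA
CTACCGGCTCGTATTATTGTTTCGGGAATAATACAACATTTAAGATCCACGACGCGCTACCTGGATTGGG
CCGCACATAATCAATCTTTTGAGGCCGTTAGCAGCGTTTAATATACTTGTGTGGGTATGTGCTTTTGGAC
CAGTCACCAGCAGAGTGGTCCTTACCCTACATTGTGGACGCAGTGACTACCGCCCGCGGGATCACGGACG
AGGCCCTTTCGTCTTCAAGAA
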