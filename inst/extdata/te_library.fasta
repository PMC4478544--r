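>synthetic_retroelement_1 length=1500 (synthetic sequence, fixed-seed random; no real TE content)
GGCACAGCTTGGGAGACTTTACCAGCACTATCCATTTCGGCTTATGGTATCCCAACACTGGCGGACGGGC
AGATTAAGCCCAAACGTGCCGTCTTTATTTCTTGATGACATTGGCACCGTTGGTGGAATCGTCCCGCTCT
GAATGATCCACGGATCAAGATCGATGACAAGCTCAACTCAGGGCCCTCGTGTTACCCTCCCTCTGCAGTC
CTCTAGTCTCCAAAGCAGCAAATGGCGCTGCGGCACTCTAGGAGGGCGAACCTGTACTCAAAAGGAAAAG
TGCTGATATTGTACAATGGGCACATAGTGCGCAGCAAATCTGTAAGAATGGTCAAGCATCGACCCCTTCG
AGTCTCTCACCTACCTGCCAAGTAACCCTCATAATGGCTGAAACGGCAAGCTAGATTACCGCCTCATATC
TCGTCCTATTGGGATCGGTCATCTTAGTCACCTCCCGCGCCAAATCGACTCTATTAGTCAACTCCTTTTC
AACTGACATGTCGGGTGGACTCGGGTATTTGGTGACTCCCTCTACAGTCAGGGTGCAGGTGCAAGGATAT
AGAACCTCCTCAGTTCAGACCGCATCTGCTGACTTCGGGCGATTCGTACGTCTCGCTTATTGCCCAACGC
GCTTTGCCTAATGGAGTACTCATTCGCGTCGTTAGTTAGCAAGTATCTGTCCGATGGTAGTAGAGAGTAG
CTGACCGGGATCACATTTCCTACCAGCAGGGCACGGGAGATATCATTGAATGAGCAATATACGTCTCCGA
TGTTTGTCGGAGCGGCCAATTACAACCGCGGAGTGGTAAGCTTTTATTATGAAGTAACCTAAACTATGGG
AGGACCAGTCCTTCATCTGGCAAGGAGGCAGCGCGGGAGCAGCGAAATACGCGGGAAACGTCCGTCTGCA
TCCTAGCGACATTAGAACTGGATTCTTTGCTAGGCTTGAATGAAGTCGATAGATCTCCAATTTCGATAGA
CATACCCCCGGTGGGTTCGGAACAATTTGACTGCACTTTTTCTCGTAAGTTGAAAAGGCTCTTAGCGCAT
GCGGGTTGATTCGCGGCCTACAAAAAAGGTGTGCGGGACCAAAACCAATGGAGCGAAACCACTTGATACC
AAGCCATGCAGGTGGGCAACCTTGACCTCTCAACCACAACAGTTTAATGTGGCGGGGGCCGACTGGCGGT
ATATTAACGCCATGTATGGAGTTGCTGAACCACCCCGCGTAGAGCGTACCTCCGGTTGGTTCTCGTTCTT
ATTTAGAAATGTGCTTCTGGATGCCCTTCGAGAAATACGTAACCTAATCATACATCAAATTATCGATAAC
GCCAGACCTGTAGTGCACTATCTGACTACATGAGGTTGCAGGTAGATTATTGGCATTAATAATACCCCGC
TATTCTCCGCTTAAGGACAGCTACCGGCATAATCCTTTAGGCGTTCCTCAAGTAGCGCATTTCACGATGC
CCAGGTTTCGCACGAGCGTACTACTATAAG
>synthetic_retroelement_2 length=1200 (synthetic sequence, fixed-seed random; no real TE content)
AATGAATCCACGACTAGTTGTCCTCCTCAGTTAGTGAGGAACCTAGAGAGACCTTATAGGCACTGGAATG
CCCCTTTTGGCTCTCCGCCGAGGAGGGAACTTGGTTCTCTTCAGATGCTCACCTACAGGTCGTGGTCAGC
ACGTTCGCTTGATGCGCGTATGCTCCGACGACGGGCTAAGCTGTCTCTCAATGTGCCGGGAGATATATTG
ACTCACGGAAGTCCACCCGGCATTGCACTAATAGGAACGCTCGCCAGATTGTTGATAACTGTCCGTGAGG
CCGGTCTACAACCGCGGACTCGACTGATCAGAGTGACCTTCATTAATTAGCAGAACGCATTTGTCTTATG
ACTGGCTACATATGCCCGGTCGCTACCTGGGTGTCGCGAGGATACTCGCACCAGACAGCTTTCTGGACAT
GGCCAAAAGAGCTAGCCAAGAAGGAAGGTTTCTCGTTCACAGTGAGCATGCTTATTGGCACAGTCGGGTG
GCGTCTTCTCAGTTGCGGCCGCGCACGCTGATTTGTCCAGCAAGGTCTACGCGCTATAGAACTGACGTGT
ACAAGGAGGCAACAAAAACGGAGGCGTATATGCCAATCCCGTAGGCCGGGACAGGGACAGCTCGTTTGCG
GACTATTTGCATGATCCCTGAGGTTGAAATAAGGTAATTTCGACCAGTTGTGTCGCGCTATAGCTTCGCG
GCGGTCTTGCTCTTATGTGGCGTGTGCCTTTTCGTTTGTTTCAGCTTTTTCGCCCAATGGTCGGCGCACC
TTAGTCGATACCGGCATATGGCGTGAAATTTTATGAGAGCCTTTTTACCTCCTAATCGGCACTTCAGTGA
TACAACGTAAGATCATATGTGAAGAGACTAAGGGAGCCATTTATGTTCGCTAGGCAATGCGAGAGTGCGT
GTTGCGCCTAGCTCGGAACGCTTCTTATCCTCATTCCCCCGTGATTGGGTATTACTCGCTCATCCCTAAC
GAAGGTTCAAGACAACTGGTCCGGATGGACTGAAGGGGTTTTGGCGGATAACACTGCAATTTTCCCTATG
ACAGTGGTTTCACTTGAGCACTCTTAAAGTACGCCATATCTACTGGGCTACTCATTCGGTCGACTTGTTA
CGTAATGGTAGAGAACAGGCTGAACATTCATACTGCTTTACCTCCTCTTTTCGCACGATACTCAGGTTTC
AGCTAGTATG
>synthetic_retroelement_3 length=900 (synthetic sequence, fixed-seed random; no real TE content)
AGTTTCGACTGTCCTACCCGGTGTAAAGCTACCATAGTCATCCATTCTCCGTGTCGGGGCACACCAGCTC
AGCCGATGTACGTGCCTATAGATGGAGGCAAGTAGTATGCATACACCCCTCCGACTCCACTGAAGGTCGT
CGAGCTGGGCCTTCTACTCTTGCTCGTGCTAATTCCCTTTATCAACATCCGAACACGACACCGCGGTCAG
TTGCGATCTTGTAACATAGGACTAGGAAGTTCGGCAAGGGCCCACTCGTTCGCATATCCATGAGTATTAC
CGACCGCCCAGGGATAAAAATCGCGACTTCGTCATTTAATCTGTACTAGCAAATTGCGTATAATTCCCCT
TGATCGGCCCAAGCAGGGAATTTGACATCATCTGAACGAGTGACTTGATGGCAGCGCTCAAGGGCATTGG
ATCTCGGAGGATCAGGAGATTCCATATCGTAGAGCCTAACCTCTAGGACACACTTCGATAAGTGCGCGGA
GGCTGGGTGGTCGGTTCGAACTTATCTGTTAGGCACCCTCTGGATCTAACGCGTTCCGCGGGATTCCAGG
AATTCAAATGGCATTAGTGCTAGGGTGGATCACTCGGTCGAAACAGTACCAACGCAGACTGAGCCCGTAC
TTCCGCGGGAGCCGTTTATACTCTAATCGACATTGGGTAGTTGTCAACTAGAGTCGCAAGCCCATCCACC
TCTCGCGTCGGTGTAACAGTCCGATGTGACATTACAGTATGCCATTTTTCGAGGCGTTGTTGACTTCGGA
ACTCCCTGACATTTCGGGATCTTATTACCAGGCGAGGCGGCACGCGAATGCCCAATATGACTGAACGCGA
CGATACCGGACGTTCACACGATAATACGTAAATAACACAATCACTGCAATTTCACAGGAA
>synthetic_retroelement_4 length=750 (synthetic sequence, fixed-seed random; no real TE content)
GAGCTACCCCTAATGCAGAATCCGTAAACGTAACAAAGAGAATGTGGCGTAACTGAGCTATTGCTTGGCT
CAACAGGCGGAGACCCCCTTTGATCTAATTTCGAGGCGCGCACAGGGGGAACGTTATAGTCACTTAGCAC
CGGGCGTTGGGGATCGAGACGTAAGCCGAGCGTTATAGTCTGTAGGCTTCCTTGCAACACACGACTTGTC
TTATTATGAATCTTACTTGTGATTGAGTGCGGCCTCCGTGGATTTTGAAGCGGTCTAGAGGTACCATGTC
CAGTGGCCGTCGATTGCCCGATTCTAACTCCTTTTGAACGATTTCTACGCGCTCCTGCCCGGCACCGTAG
GCTGAGTTACATTGCCGAACAACCTATCGCAGCATATACCTAGAATTTACGGGTAATACTCGCGTATCAA
ATTAAAGTAGATGTACCCGTCCTGTAATGTATGGCAGCTCGTATTTAGCTTTTCTTCTCGGGATAATAAG
GCACCGGTAAAACGGCGGCTCTGACGTGCCGAAGACTGTTTCGATCTTTGGCATCTGCGCGAGAAATTTT
CTTCATACGGGCCAATGACCGTAGTGGGCCGGGCGCATGGCTCCAACGGCTGGCCAACCCCTTACGGCCG
ACCAGCTAGTACACAGACGCGAAATTGACGCGAGCTCTCACATAAAGGATTACATGCTCGGCAGCTGCTC
TACTCCTCGATTAAGCCCTTCCAATTCATGTGAGCGACTGTGGATGCGAC
>synthetic_retroelement_5 length=600 (synthetic sequence, fixed-seed random; no real TE content)
AGCTGGTCTGGAGATGGCCTGCGATAACCGTGCCCAACGCGATAGCCGCGAGTTTTTCTGCGTGTCTGCA
TCGCGGGGGGCAGATAAACACGAGTTTTCTGTCGTAGGAGTGGAAGTACGGCCCAGATACAAGCGAGGGC
GCAGCTCTGGGAAGATTCACTGAGAGTTTACCACGGTAGGATGCGACTGGGACTCTATCTCCCTTCATGG
TTGCTGCCAAGAGGTGGTTGCGTCGAGCCTCCCACTTCCGATCATGACTCGCTAAGTGTGGGTCCTGAAC
ACAATTACTAGAACACTCGCTGAGTATCTTCGGGTCACTAATTTAACGCTGACCGTCCCTGTATAGGTAT
CCGGCCGGCTCTTGTTCCCTGTACGTATACTCGAGATGTGTTATCCTAATCCCCGCGAATTCATTTATTC
TCTGTAGTGCGGTTGTAAAGGTTGTACCATATGGTACAGCCAAGACTGGTAAAGTGCTAGGTGCCTTACC
ATGAGTGCGCGCGATATGCAATAAAGACACGTGAGTGTGCCCCGAACAGGCGTCCGCCCATACTGTTAGT
GCCCAACCGCCGGTTTGGAGTTAACCCACGGTGTAGTGAC
>synthetic_retroelement_6 length=450 (synthetic sequence, fixed-seed random; no real TE content)
AGGCCTCAGCAAGAACAGCTCTTATCGGGGCATTAACCACGTTGGTTCAGTTGGGGGGCTTAAATTAGGA
TGTCACGTAATCGGATACTGCTTCCCCTGCTGTGCCGCTGAGCGTAGTGACGAGGCGCCTCTCTCTCTGA
ATCTTTCTTCGGACAGAAAGGCCAACCGATTTCCGTTACTCATAGAGCCCCCCGTCTGCTAATCGTTCAG
GGACGTAGGCTACTCCGTAGGAATGCCGTCGCTTGGAGGGACATACCCATTGTACGATAATCCGACGACT
GGTGCAGGACGATGTGTGAGACCGTGTCGGAAATGTCTGACGCAATGGCCAGAATGGTTTTGTTACCGTG
ACTAGCGTGATCGGCACCCCTAAGAGTTTAATCTAAGAGGAACAATACTGGTCCTTCGACACTATTTAAC
GTTCCATAACGCACCAAGAAAGTAGCCCGA
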