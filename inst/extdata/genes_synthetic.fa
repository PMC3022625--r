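>ACT1
AGACACAGGGCAGAACGATTATTTGGAAGCGGGCCACTGCAGGCTCAGTGCCCCTAGGCGTTATTGCAAG
CGGCTTGGGGCGCTCAGCCAACTATCACCGGTTATCAGCTGTACGGCAGCGACCGGATTCGGCCCTTTGG
GGTTGAGATAGCAGGTCCTA
>YPL122C
TGCCGGTAACGTTCCAACCAGTGACTCAGGAAAATATCGTGCCCGTTGAGGGTTGACGTTGATCCTTCAG
CAAGCTCGTGCTAGGAACCAAACGCCGGGGTAAAGGCCTAACATGTGAACCGCCTAACGAACGGTCATGT
CTGCTACACAAGGCGGAAGT
>YNR030W
CCCCAGCATAGCCCCTGAGCGGAGGTTCCGCGCGGTAGGGACTTAACCGAAATCTCGTATCAGGCTTCCC
GCCAAGGTTCCTGTGCCTGTCGCCCGTAGTGGAGGGGTTCGCGTCCCGGGCTGGGCGCCTCTAGCGCGAA
ATCCCAACACGAACTCACGG
>YDR343C
GCGGGTGGGACTGGCCGGCCTATCACTCCCGCATTGGGCCCATATGGGTCGTCAGTCTGCTACATCTGAC
TACGACTGCCTCCGCACGTCCGCGGCGGGAAATGCCTCCATCTCATGCCCATCACGGCGAGACTTGGGTT
CTCACCCTCCAATTGTCGGA
>YGR088W
ATTGCGAGCAGTCACGGTCCATCAGGCCATCAGCATCGCCTGCATTCGCGCGAGACCGGACTCGTCTGTT
GCAGGCGATCAGACCGACTCGTCGCGGCACGACGCTCGCTAACTTCGAGAGTCCATTAGGCTGGGGATCA
TCCTCCTAATTCCCCTAGCC
>YPR149W
GCTTACGAGACTCGCGGGGCGCCCTGTCGGCCGCCAGTTTCTGACAGCGCTGGCGACTGGACCAGTCGCG
GAGATTCCCCTTAGCTACCCCCGTTAGGCCCTCTACTGTTCCGTAGCTCCTACGTGATGCGCCTGTCCTA
GGCGAGCCTTCATGCTGTCG
>YCL040W
TTATCAGGCGTTCCGTTGTCTGCGCCTTACCTGAAAGAACAGGATGAAGGAGCTACCGTCTCAGTCCGGG
AGCGCCACACTTGACTCAGCATAGGCGCCAAAATCACCCTTCTATAGGGCTGGGCCGGGTTCTATGTCCG
CGTGAAGGATCGACCGGGGA
>YBR054W
TATACCCATGGGAGTTGGAGCGCGGCCTGCTGTCAGGCACCAGTAAGTGCGTCAGGAAGGGGCGGGGCTT
GGTCGTGGCGTAGGGGCTGGCTAAAAGCCTTACGACTATACGAGTCAAGCCACCTCTTTTATCACAGCCA
TGCAACATCGGAGATGCTCC
>YNR001C
CGGCTGTGCCTCACGCTTCAGGAACACGGGGTCCCAGCCACACCCACCTGCATCCGCCTGGACCTGGCAA
TGGGTTTCGTAGCCGCCTCGGGGGTAGAGCCCGAGTCCGATCGAGGGGAGAGGGCGATCCACGCTCGGCG
AAGCCCGCGCTTAGACGGAG
>YDR533C
CGACCGTGGGCTAAGCGGATATACCGCTTTTGGTCATGGTGACTCTGTTCGCACGACTCCGCGCCATCCG
GCGCCGCACAAACGCGGGTCCGAAGGGAGCTGTATGGCCCCGCCCCGGCTAATGGACCCTGCGAAGGACA
ACGTCCTGTAAGGCGCGCAA
>YDL222C
GTATGTACGCCAGCGCGTGCCCGCCGTACTCAGACCGCGTAATCACGGAGAAGACGGCGCCTGACACCTC
CCGGCCGCAAATGGGGCCACGTTAGCGAAGGCGAACGACGAAGAGATTAGCAACGCGGTCGACTTCCGTC
CCAAAGCAGCGGGCGAGCTG
>YML123C
GCGCCACGAATGTCCACTTAGCGCGGCACGCGCGCGGCATTAAAACTCAGATGCCCGGCGCTGCAAAGGG
GGGAGACTAGCCCTCCGAGCCAGCCTGCCCGCAGTACTCAACCGAACAAGGGTTATAGACCCGACATGGA
CGAGGGTGCACGCCGTAGCA
>YEL046C
GAAGACCTCACGAGTACAGCCTAATTGTGTCGGGTTGTCGGTGACCCTCCCATGCGCACCCTGCCACCCC
GTCCGCGGTGGGACGTCACCGCCAAAGCGTACGCTCCGAATCAGGGGTGTAATCCCCTAGCGCCTGTTTC
AGTCTGACTACGTAGCTCAT
>YLR180W
GCGGGGCGACGCGCAGGGATACGGGGCATCACCTCGAGCTTAGTGTCTCACGCGGGTAATCATAATCGTC
CTTATCGGTACCGAGGCAAGCTCCTCTATCACATGGCGCAAGTAGGACAAGCCATCCAGCTGTTATCCAT
CAATGGTCTTGGATGCTTCA
>YLR355C
GTTGCGGGCGCCGCGTTCGTCCGCCCTGATTTACCGTCGTGGCGCGGTGCCTTGACGTCACACGATACCG
CGGCCTGTCCCTGTGTTTTGACTGACCGGTGTTCGGCAAGTACAAACTGAACCATGCAGCGCGCCGTTCG
TTCGAAGGGTGGGATGCATC
>YLR419W
GTGACGCGTGGAGCGCGATCCTCTGTACACTAATGGCTCCCCCACGGGGTGCAATGTCTGGGCGCTGTGG
CAACGTTCGACAGGCCAGTGTGCTCAACAGTTAATGAGCGGTAGACGGGCTCGACTTTTAGCCGGTCACG
ACTCCTGTTCGGGCTCTTCC
>YLR300W
GCGGCACTTGCGAGAGCGGGGAGCTCACTCCGAGATACTATTCCCAAGCGTATCAATTCTAACGTGCCGT
CGCAGACCAACCCGCGACGTGTTTATTGCCTGAATCGAGTGCGCGGCATACGGGGCCAAATTGTGGAGAG
CATAGGGCCCTTGCCATATC
>YNL300W
TCACCGCTCCCAGCATCGGCACGCCTACCGTGTCGAAACCCTACGCCCGACGTCGCTCCGCCGCCACCGT
TCGCTAGTGTCGGGTATCTGGATTCTCTGACCCTGGGTGGGGGGCCGAGTTTGAGAACTTTCGTTAGCCT
CACCCGCCTAAGGGCCTCAC
>YLR372W
CGGCACTTCGATCTATCGTCTAGTCCGTAGATAAGGCTCCCTGCCCCTGTAATCGCCACGCCTCCTCCGG
TCGCGTGAACCTGTCATGAGCCTCGCGAGGGTGCGCTGACTTTTGCATATAGTCGGAGCATACCGCTACC
AGGGTAGGGCAACACGGGTC
>YAL059W
TCGGGGGTGATCCGCTCGACGGAAGGAGCGCGGGCGCCGTGTGCGAACCTATGGCCATGGGCGATGCGAC
ATATTCCGTGCGCGGCTGGTCGTCCCGTGGAGGACGGTCCGACCGCAATCCCGTCTCCAATTCCGCCGCA
TTTCGGGGCCATCAAGCCTA
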