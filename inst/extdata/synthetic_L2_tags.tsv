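tag_seq	count
CATGAACGCCACCAAGTTAAA	1
CATGAACGCCACCAAGTTGAA	93
CATGAAGCAACCACCCTGTCT	1
CATGAAGCAATTTTAAACGGA	31
CATGAATATCGACTAAATATC	1
CATGAATCAAGACAAGCCGGG	1
CATGAATCGTAGTAGGACGGG	1
CATGAATTGCGCTCGCCTTTG	1
CATGACAGGTGCCCTGCCCGG	1
CATGACCATCGATCCCGATTA	1
CATGACTGCGCGAGTCACGCC	64
CATGACTGCGCGTGTCACGCC	1
CATGAGCAGTAGGACATCTTG	1
CATGAGCGGCTTTGCTCTATG	1
CATGAGCGTAGCCCGGCGCCG	1
CATGAGCTAATGGACCAATAA	1
CATGATAATATCCCCCCGATC	1
CATGATACTTAGAGGTGCACC	1
CATGATAGTATCCCCCCAATC	1
CATGATAGTATCCCCCCGAAC	1
CATGATAGTATCCCCCCGATC	123
CATGATAGTATCNCCCCGATC	1
CATGATAGTCTCCCCCCGATC	1
CATGATATTATTTGACACAAT	1
CATGATCGCCACCAAGTTGAA	1
CATGATGCCGAGATCACTGCA	1
CATGATGGTATCCCCCCGATC	1
CATGATTTCTTCATATCCAAA	1
CATGCAAGTTCGGATTGCCTG	18
CATGCAGACTTTAAAAGACCC	1
CATGCAGCATACTCCCGCTAT	23
CATGCCCCCATTTGCGTCCGG	1
CATGCCCGAGAGTTCCATTTA	1
CATGCCGAGCCGTTAACTAAT	1
CATGCCTTAAGCCGTGAGTCA	1
CATGCGACTCCTCGTAAGACT	11
CATGCGCCCAATTATTACTGA	1
CATGCGGAGTACGCGAGCGCA	1
CATGCGGGAACCCTGCAAGGT	1
CATGCGTCAACCCGATTCTGG	1
CATGCTCCAAAAACACAATAG	14
CATGCTCGATCAATCAGGGAG	1
CATGCTCTTTTTAGTGATGTG	1
CATGCTCTTTTTAGTGATGTT	7
CATGCTGAATTTGCGCGTTTC	1
CATGCTGACATTGCGCGTTTC	1
CATGCTGACNTTGCGCGTTTC	1
CATGCTGACTTCGCGCGTTTC	1
CATGCTGACTTTGAGCGTTTC	1
CATGCTGACTTTGCGCATTTC	2
CATGCTGACTTTGCGCCTTTC	1
CATGCTGACTTTGCGCGGTTC	1
CATGCTGACTTTGCGCGTTGC	1
CATGCTGACTTTGCGCGTTTC	555
CATGCTGACTTTGTGCGTTTC	1
CATGCTGACTTTTCGCGTTTC	2
CATGCTGCCTTTGCGCGTTTC	1
CATGCTTCATTTACTACACCC	6
CATGGACATACCCGCTTTCGG	58
CATGGACCAATGCGATGGCCC	1
CATGGAGCTTAGAGTGCCTCG	1
CATGGAGTTAACCAGGGCTGG	1
CATGGAGTTAGCCAGGGCTGG	15
CATGGATTTAGCCAGGGCTGG	1
CATGGATTTGGGCTTAAGGAC	1
CATGGCACACTCTAAGATGGG	57
CATGGCATAAAAGCCCCGTAA	1
CATGGCCAATTTACGATGGAG	1
CATGGCCAATTTATGATGGAG	8
CATGGCCATAGACAGACGCTG	1
CATGGCCCCATTCGCGTCCGG	1
CATGGCCCCATTTGCGTCAGG	1
CATGGCCCCATTTGCGTCCGG	178
CATGGCCCCATTTTCGTCCGG	1
CATGGCTATAGACAAACGCTG	1
CATGGCTATAGACAGACGCTG	18
CATGGCTGTGGACACTGCCCA	1
CATGGCTTCACCCGCCTTGTA	1
CATGGCTTCTAGCAAACTTGT	1
CATGGGACTAGCCCAACGTTA	1
CATGGGAGGCGCTGGCCATAT	6
CATGGGAGGGGCTGGCCATAT	1
CATGGGAGTGGACACTGCCCA	1
CATGGGCCATCCACGTCTCTG	1
CATGGGGAGAAATGTAACGTA	20
CATGGGGTATCCCTCTTAGGG	1
CATGGGTATGGACACTGCCCA	2
CATGGGTGCGGACACTGCCCA	1
CATGGGTGTGGACACAGCCCA	1
CATGGGTGTGGACACTGCCAA	1
CATGGGTGTGGACACTGCCCA	456
CATGGGTGTGGACACTGCCCC	1
CATGGGTGTGGACACTGCCCT	1
CATGGGTGTGGACGCTGCCCA	1
CATGGGTGTGGAGACTGCCCA	1
CATGGGTGTGGATACTGCCCA	1
CATGGGTGTGTACACTGCCCA	1
CATGGGTGTNGACACTGCCCA	1
CATGGTACCCATATGTTAGCC	53
CATGGTACCCATCTGTTAGCC	1
CATGGTATGCAGGACCCGTGT	4
CATGGTCGTAAGTGTGCCAGG	1
CATGGTCTGTATGAAACTAGG	49
CATGGTCTGTATGAAGCTAGG	1
CATGGTGCTTTAGCCCACTTT	1
CATGGTGTGAGTGTTCGTACT	1
CATGGTTAATAGCGGTCCGAT	1
CATGGTTAATGATGGTTTACT	1
CATGGTTCTTCTTGATGAGGA	1
CATGGTTTCGTTAGCAGTCAG	1
CATGTACGCTGCGACAGTGTA	8
CATGTACTTACGTCGCTGCTT	1
CATGTACTTCGCCTGGGATGC	1
CATGTAGATACGTCGCTGCTT	1
CATGTAGCTCAGTAGACGATC	23
CATGTAGTTACGCCGCTGCTT	1
CATGTAGTTACGTCGCTGATT	2
CATGTAGTTACGTCGCTGCTT	314
CATGTAGTTACGTCTCTGCTT	1
CATGTAGTTACTTCGCTGCTT	2
CATGTAGTTCCGTCGCTGCTT	1
CATGTCACGTCCAATCCGAAA	1
CATGTCCGCTTGATCATGTCT	2
CATGTCGTCGGTGAAGCCAGA	13
CATGTCTCGTCCAACCCGAAA	1
CATGTCTCGTCCAATCCAAAA	1
CATGTCTCGTCCAATCCGAAA	102
CATGTCTCGTCCAATGCGAAA	1
CATGTCTCGTCCNATCCGAAA	1
CATGTCTCGTCGAATCCGAAA	1
CATGTGCCATAGACACTACTC	1
CATGTGCCATAGACCCTACTC	1
CATGTGGGCGCTGTTGAGTTA	1
CATGTGGTATGTGGGGTCGGT	26
CATGTGTCAGCAACAACCATT	1
CATGTGTGTGCTCAACTAGAA	1
CATGTGTGTGGACACTGCCCA	1
CATGTTAGTACCATTTACCGT	1
CATGTTGACTAAATGCTCCAA	1
CATGTTGACTTTGCGCGTTTC	1
CATGTTGTACTCAAATGATCG	1
CATGTTGTATGTGGGGTCGGT	1
CATGTTTATAGGGCAAGTTTG	1
CATGTTTGGCACACGTATTTG	1
CATGTTTGGTATACTGCGAGC	1
CATGTTTGTTATACTGCGAGC	25
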