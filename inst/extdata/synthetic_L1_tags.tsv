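tag_seq	count
CATGAAATTTCCTGAATCAAC	1
CATGAACAAGGCTTTACGTCA	1
CATGAACGCCACCAAGTTGAA	137
CATGAACGCCACCAAGTTTAA	1
CATGAACGCCACCAGGTTGAA	1
CATGAAGCAATTTTAAACGGA	48
CATGAAGTCCCTTCAGCACGA	1
CATGAATACGGTGGAACGCCT	1
CATGACGCACATTCGCAATCA	1
CATGACGGAGAGATCAGTTAC	1
CATGACTGCGCAAGTCACGCC	1
CATGACTGCGCGAGTCACGCC	134
CATGACTGCGCGAGTCACGCT	1
CATGACTGCGCGAGTCACGGC	1
CATGACTGCGCGAGTCAGGCC	1
CATGACTGCGCGAGTCGCGCC	1
CATGACTGCNCGAGTCACGCC	1
CATGAGACGGCTAACTCGATC	1
CATGAGTAACCTGGGATCTCT	1
CATGATAGCATCCCCCCGATC	1
CATGATAGTATCCCCCCGATC	29
CATGATATAAGTTGAGCCCTC	1
CATGATGAACTCGCAATCGAG	1
CATGATGACTTTGCGCGTTTC	1
CATGATGCAATTTTAAACGGA	1
CATGCAACGATGGGTTCGCCA	1
CATGCAAGTTCGGATTACCTG	1
CATGCAAGTTCGGATTGCCTG	24
CATGCACCTTGCTGATCGGTG	1
CATGCACTGTGGGAGCCCGCC	1
CATGCAGCATACTCCCGCTAT	41
CATGCCCGTGTTCAGTCAGAC	1
CATGCCGATCGGCTCTTACTA	1
CATGCCGGTCGGGCAAAACCG	1
CATGCCGTCGGCCCAAAGTTT	1
CATGCGACTCCTCGTAAGACT	44
CATGCGACTCTTCGTAAGACT	2
CATGCGCCGTGGTAAGCGTCA	1
CATGCGCCTCCTCGTAAGACT	1
CATGCGCGACGGGACAGACGG	1
CATGCGGCTGCCCGTCCGACC	1
CATGCGTACATTGACTGGGGA	1
CATGCTAACTTTGCGCGTTTC	1
CATGCTATCAGCCGTGTTAAT	1
CATGCTATCGGCTTGCCACAT	1
CATGCTCCAAAAACACAACAG	1
CATGCTCCAAAAACACAATAG	20
CATGCTCTGACGTGGGCGATC	1
CATGCTCTTTTNAGTGATGTT	1
CATGCTCTTTTTAGTGATGTT	108
CATGCTCTTTTTAGTGTTGTT	1
CATGCTGAATTTGCGCGTTTC	1
CATGCTGACATTGCGCGTTTC	1
CATGCTGACTATGCGCGTTTC	1
CATGCTGACTGTGCGCGTTTC	1
CATGCTGACTNTGCGCGTTTC	1
CATGCTGACTTTCCGCGTTTC	1
CATGCTGACTTTGAGCGTTTC	1
CATGCTGACTTTGCACGTTTC	1
CATGCTGACTTTGCGCGGTTC	1
CATGCTGACTTTGCGCGTGTC	2
CATGCTGACTTTGCGCGTTAC	1
CATGCTGACTTTGCGCGTTCC	2
CATGCTGACTTTGCGCGTTGC	3
CATGCTGACTTTGCGCGTTTA	1
CATGCTGACTTTGCGCGTTTC	879
CATGCTGACTTTGCGCGTTTG	1
CATGCTGACTTTGCGCTTTTC	1
CATGCTGACTTTGCTCGTTTC	1
CATGCTGACTTTGGGCGTTTC	1
CATGCTGACTTTGTGCGTTTC	4
CATGCTGACTTTTCGCGTTTC	1
CATGCTGAGTTTGCGCGTTTC	1
CATGCTGATTTTGCGCGTTTC	1
CATGCTGCCTTTGCGCGTTTC	1
CATGCTGCGTTTAGTTGAGTT	1
CATGCTGGCTTTGCGCGTTTC	1
CATGCTGTCTTTGCGCGTTTC	2
CATGCTGTTTTTAGTGATGTT	1
CATGCTTACTTTGCGCGTTTC	2
CATGCTTAGCATGGATGCATG	1
CATGCTTCATTTACTACACCC	15
CATGCTTGGCTGTTCGGCATT	1
CATGCTTTTTACTAGGCATCC	1
CATGGAACATGTCTACGTGAC	1
CATGGAACGTATGCTCTTTAC	1
CATGGAACTACGCACCCGGGA	1
CATGGACATACCAGCTTTCGG	1
CATGGACATACCCGCTTTCGG	100
CATGGACTGCAACTTTCCAAA	1
CATGGAGTTAGCAAGGGCTGG	2
CATGGAGTTAGCCAGGGCCGG	1
CATGGAGTTAGCCAGGGCTGG	34
CATGGCAATGTGCGTTCCTTG	1
CATGGCACACTCTAAGATGGG	5
CATGGCAGTTGGAGTAGGTTC	1
CATGGCCAATTTATGAAGGAG	1
CATGGCCAATTTATGATGGAG	39
CATGGCCAATTTGTGATGGAG	1
CATGGCCCCATTTGCGTCCGG	39
CATGGCCCGTGGAGACAGACA	1
CATGGCGTCGGTGAAGCCAGA	1
CATGGCTATAGACAGACGCCG	1
CATGGCTATAGACAGACGCTG	36
CATGGCTATAGACAGACTCTG	1
CATGGCTATAGACAGNCGCTG	1
CATGGGACCCTCTAGGAAGTA	1
CATGGGAGGCGCTGGCCATAT	14
CATGGGCAAACCAAGTATGCG	1
CATGGGGAGAAATGTAACGTA	25
CATGGGTGTGCACACTGCCCA	1
CATGGGTGTGGACACTGCCCA	116
CATGGGTTTAGAGTGGCGTAC	1
CATGGTACCCATATCTTAGCC	1
CATGGTACCCATATGTTAGCC	87
CATGGTATAGAGCGTACACGC	1
CATGGTATGCAGGACCCGTGT	3
CATGGTCATACCCGCTTTCGG	1
CATGGTCTGNATGAAACTAGG	1
CATGGTCTGTATGAAACTAGG	96
CATGGTCTGTATGAAACTAGT	1
CATGGTCTGTATGAAGCTAGG	1
CATGGTCTGTTTGAAACTAGG	1
CATGGTGAGTTGGCACCCAGT	1
CATGGTGCTCCCCGGAGAAAC	1
CATGGTGGGAGTGAGTGATTC	1
CATGGTGTGTATGAAACTAGG	1
CATGGTTCTTTAACTGTTGTA	1
CATGTAACTCAGGTCTAGTGC	1
CATGTAATGGAGCGTACATAG	1
CATGTACGCTGCGACAGTGTA	6
CATGTACTGCCAGATCTTAGG	1
CATGTAGCTCAGTAGACGATC	33
CATGTAGTCGGGGCGTACCAT	1
CATGTAGTTACGACGCTGCTT	1
CATGTAGTTACGTCGCCGCTT	1
CATGTAGTTACGTCGCTGCTT	76
CATGTCCAGCGATACTGCGGT	1
CATGTCCGCTTGATCATGTCT	6
CATGTCCTATCAACCTTGTCA	1
CATGTCGTCGGTGAAGCAAGA	1
CATGTCGTCGGTGAAGCCAGA	22
CATGTCGTCGGTGAAGCCATA	1
CATGTCGTCGGTGAAGCCCGA	1
CATGTCTCGTCCAATCCGAAA	24
CATGTGACGCTTGGATTACCA	1
CATGTGCCATAGACACTACTC	7
CATGTGGTATGTGGGGTCGGT	52
CATGTGTAGGATGTTTCAGTT	1
CATGTGTATAGGGCAAGTTTG	1
CATGTTACTCTGGGTATATAT	1
CATGTTGATGCGGAGGATTGC	1
CATGTTGTCGTAATCTATGGA	1
CATGTTTATAGGGCAAGTTTG	16
CATGTTTGTTATACTGCAAGC	1
CATGTTTGTTATACTGCGAGC	49
CATGTTTGTTATACTGCTAGC	1
CATGTTTGTTATACTGGGAGC	1
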