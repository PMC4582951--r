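>AluSyn1
AGTCCAGACGCCTCGCTCAGTGAAACTGAATCCCGAGAAGAGTGACCAAATTTTTGCCGCCGTTGTGGGGGTATCTGGTA
AACTGCCTGGGCACTTGGACGGGGTGATGCTGCTTTTACAGGTCTGTCTCAAAGATAATAAAAAAAGATAAATGCTTTCA
CACACCGAGTAATAGTCGGACGGAGTGTCGTAAGCACTTCACGTTTCGGAGGTATGAACTTGCGAGAGATGGGTTTTCTC
CAAACGAGACTGTCATTGTTTGACTTGGCGAGGCAGAGTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>AluSyn2
AGCCGAGGCGCCTCGCTCAGTGAAACTGAGTCCCGAGAAAAGTGAGCAAATATTTGCCGCCGTCGTCGGGGTATCTGGTA
AACTGGCTGGGCACTCGGAGGGGGTGACTCTGCTTTTACTGGTCTGTCTCAAAGATAATAAAAAAAAAAAAATGCTCTCA
CACACCGAGTAATAGTGCGACGGAGTGTCGTAAGCATTTCACGTATCGGAGGTATGGACTTGCGAGAGATGGGTTTTATC
AAAAGGAGAATGCCATTGGTTGACTTGGGTAGGCAGAGGGAAAAAAAAAAAAAAAAAAAAAA
>AluSyn3
TGCCCAGACGCCTCGCTCAGTGAAACTGAGTCTCGAGAAGAGTGAGCAAATTTTTCCCGCCTTTGTGGGGGTGTCTGGTA
AACTGGCTGGGCACTTGGACGGGGTGACTCTGCTTTTACAGGTGTTTCTCAAAGATAATAAAAAAAAAACAATGCTCTCA
CAGAACGAGTAATAGTGGGATGGAGTGTGGTAAGCATTTCATGTATCGGAGGTATGGACCTGCGAGAGATGGGTTTTCTC
CAAACGAGACTGCCATTGGTTGACTTGGCTAGGCCGAGTGAAAAAAAAAAAAAAAAAAAAA
>AluSyn4
TGCCCAGACGCCTCGTTCAGTGAAACTGAGTCCCGAGAAGAGTGAGCAAATTTTTGCCGGCGTTGTGGGGGTATCTGGTC
AACTGCCTGGGAACTTGGAAGGGGTGACTCTGAATTTACAGGTCTGTCTTAAATATAATAAAAAAAAACAAATGCTCCCA
CACACCGAGTAATAGTGGGACGGAGTGTCGTAAGCATTTCACGTATCGGAGGTATCCACCTGCGAGAAATGGGTTTTCTC
CAAACGAGACTGCCATTGGTTGACTCGGCTAGGCAGAGTGAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>AluSyn5
AGGCCAGACGCCTCTCTCAGTGAACCTGAGTCCGGAGAAGAGTGAGCAAATTTTTGCCGCCGTTCTGGGGGTATCTTGTA
AACTGCCTGGGCACTTGGACGGGGTGACTCTGCTTTTACAGGTCTGTCTCAAAGATAATAAAAAACATAAAATGCTCTCA
CACACCGAGTAATAGTGGGACGGAGTGTTGTAAGCATTTCAAGTATCGGAGGAATGGACCTGCGAGAGATGGGTTTTCTC
CAAACGAGACTGCCATTGGTTGACTTGACTAGGCAGAGTGAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>AluSyn6
AGCCCAAACGCCTCGCTCAGTGAAACTGAGTCCCTAGAAGAGTCAGCAAATTTTTGGCGCAGTTGTGTGGGTATCTGGTA
AACTGCCTGGGCACTTGGACGGGGTGACTCTGCTTTTACACGTCTGTCTCAAAGACAATAAAAAAAAAAAAATGCTCTCA
CACACCGAGTAATAGTGGGCCGGAGTGTCGTAAGCATTTCACGTATCGGAGGTTTGGACCTGCGGGAGATGGGTTTTATC
CAAACGAGCCTGCCATTGGTTGAGGTGGCAAGGCTGAGTGAAAAAAAAAAAAAAAAAAAAAAAAAAA
>AluSyn7
CGCCCAGACTCCTCGCTCAGAGAAACTGATTCCCGCGAAGGGTGAGCAAATTTTTGCCGCCGTTGTGAGGATATCTGGTC
AACAGCCGAGGCACTTGAACGGGGTGACTCTGCTTGTACAGGTCTGTCTCAAAGATAAAAAAAAAAAAAAAATGCTCTCA
CACAACGAGTAATAGTCGGACGGAGTGTCATAAGCAATTCACGCAGCGGAGGTATGGACCTGCGAGAGATGGGTACTCCC
CCAACGAGGGTGCAATTGGTTGACTTGGCTAGGCAGAGTGAAAAAAAAAAAAAAAAA
>AluSyn8
AGCTCCGACGGCTCGCTCAGTGAAACTGAGTCCCGAGAAGAGTGAGCAAATTTTTGACGCCGTGGTGGGGGTATCTGATA
AACTGCCTGGGCACTTGGACGGGGTCACTCTATTTTTACAGGTCTGTCTCAAAGATAATCAAATAACAAAAATGCTCTCA
GACACCGAGTAATAGAGGGACGGAGTGTCGTAAGCATTTCACGTATCGGAGGTATGGACCTACAACAGATGGGTTTTCTC
CAAACCAGACTGCCATTGGTTGACTTGGCAAGGCAGAGTGAAAAAAAAAAAAAAAAAAAAAAAAAAAA
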