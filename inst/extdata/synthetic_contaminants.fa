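>synthetic_virus_1
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCC
AGTTTTCCCCATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACG
CTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCACACTGTCCGGTGATAACCTGG
CCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGC
TGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATC
GCTATTGTAACTACGCGACTCTGGCTTTAACCGTTGTGTCGTATGCTGCGCGAGAGGAAA
AGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTCCACACCAACGGCACAGCTAG
GACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCAC
CGTACCCTAGAGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGT
CGTCGATTTTTACATGACTGAGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGT
GGACACTGAAAAATCTAGTG
>synthetic_virus_2
TTCCGTCTCGTCCTCATATATGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACT
ACGACTTATTAGTAACAACAGGATTGTGAAACTTTAGGAAGTTCTTATTTCAAAGCTGGT
CTGAGACGAAATAGTCCTACCTTATCAAGAGTACTATAACGCGGTGATAAAGGGAGTTGC
ATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGGTCCTCTGTTAAAAGGCAATG
CGTATTTAGTCTTAGGTATGAAGGCTTGTGAGGAGGGTCCTGGTGACATGTCTCATAACG
CAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGCCGCGGGAACATAGGCTTGTT
TTATAATGACGGCTCGTGTA
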