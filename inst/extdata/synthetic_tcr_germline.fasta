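>TRAV1 segment=V chain=TRA
AAACATTTCGCTTGAAGTGTGGGAGCAGATTGTGTGACCTAGGTATGTCTCCTAGTATCA
>TRAV2 segment=V chain=TRA
GGCTCAAGTCGGTCAATCTCTGGCGGGTGACGCTAAGCGCACGGTTGTGAAATCACGGTG
>TRAV3 segment=V chain=TRA
CTTCAGACCCGGGGCCATTAAAAACGAATGATGGCCACTTAACAATGTAGTCGTGGAGAG
>TRAV4 segment=V chain=TRA
CACCTACCTAACCTCACCATTCGAGCCACCCTTCAGTCTTAAGCCTGTACTACGCACAAA
>TRAV5 segment=V chain=TRA
CGACTTTTGGACCGAAGCCGGAGTGTAGTTTGGGAAGGGGTGCTTTGTGTACAATTACGT
>TRAV6 segment=V chain=TRA
AGGATGTTTCGAATAGACCGCGGCCCTTTAACAATAGCATGATTGTGTATGCAAGCCGTT
>TRAV7 segment=V chain=TRA
AACCCTGCAAGTCCCCAAGGGGACTTTCAAGAACTAGAGGCGGCTTGTTCCTCCCCTTCT
>TRAV8 segment=V chain=TRA
GCATTGCCCCAAGGGTAATCGCTAACGTCTGTGGACGCGTCCAAGTGTCCTGGGCCAGAA
>TRAV9 segment=V chain=TRA
GCAACCTTCATTTATTAGTCAGTTTGTTCCGTAGCCGAATACACCTGTGCCCACAGGATT
>TRAV10 segment=V chain=TRA
GCCGACATCGGATCCCGATTTTTAGGGCGTTAGCACTTTTAAGATTGTAACTGCGACCAA
>TRAJ1 segment=J chain=TRA
CCTCCTTTTTTCACCTCAACGACCCGATATCAGATATTCTGTCCC
>TRAJ2 segment=J chain=TRA
AACGATTGGGACCTAAGCACCGCGGAGGTGCGCCGCAAGTTAACA
>TRAJ3 segment=J chain=TRA
TGTAAGAGAAGGGTGGTTTTGATCCGGGGCATCCAAAGAGGAATG
>TRAJ4 segment=J chain=TRA
AGGGCTTCTAGGGCAGTTTCATGCCGGTAGTACCATTTAATAGAA
>TRAJ5 segment=J chain=TRA
ATCCGTCTTAATAAAGAGAAAGACAGTCTGGTTTCAATCCTAGAC
>TRBV1 segment=V chain=TRB
GTGACCTTCACCGTAGCGAGATGCGCCGAAAGAATCTAAGCATACTGTTATGGAATTCCA
>TRBV2 segment=V chain=TRB
GTAGGGACTGCGGCAAACTTACTCGGGACCCGGTACGATATTCGCTGTACTGCTTTTACA
>TRBV3 segment=V chain=TRB
CAACTTTAGAACTGTTGACTATAGCGTCTCATTTTTTGGGGCTTCTGTGAGTTCGGGCGG
>TRBV4 segment=V chain=TRB
CAGGGGCGCCCAATGAACTGAGTTCCTATGATCTATACATGCGATTGTTATACATCCACA
>TRBV5 segment=V chain=TRB
GGCTCGCTTGCGTCGAAGCCAGGTCAGGCTCTCCGGCAGGGGAAGTGTGGGGTTCCTGAA
>TRBV6 segment=V chain=TRB
GCGCCGAGTGATTATTGAAATCGGAATGCGCCGCGTGCTCAAATGTGTGGCCGATCCTTC
>TRBV7 segment=V chain=TRB
CTCCGAATGCATTTGGGAAAGGGAGATTTTACTTCATACACGGTCTGTGATCTTAATAAG
>TRBV8 segment=V chain=TRB
AATGGTCTGGTAATTGGTCAATACGTGACCTACGAGGTGCGCGGATGTTCATTGGCGGGT
>TRBV9 segment=V chain=TRB
ACGCTAGGGCCTAGACCCTTGCCATAATAAATTTACTGTCGTTGTTGTGCCTTCCGCTCC
>TRBV10 segment=V chain=TRB
AATCTAATAACCCATTAAATGATTAGGGTGGTTAGGCCTTGCTCCTGTATACGCTATGTG
>TRBJ1 segment=J chain=TRB
GGGCTGCCGACGGGCCTTGTAATACACTCTGTGGGGGCCATCACC
>TRBJ2 segment=J chain=TRB
CAATCCACGGACGATTCATCTTACTTAAGGGATCGGTTCGATTCT
>TRBJ3 segment=J chain=TRB
CGATTGATATGTGTCCGGACTAACCTCATGAAACGTCGACCGTGA
>TRBJ4 segment=J chain=TRB
ATGACCATTGTTGGGATCTCCTGGACCCTGGTCACATCTACCACT
>TRBJ5 segment=J chain=TRB
ACCATGGACCACGATTTCGCATTCCGTAACCAGACGAAGTACTGA
>TRGV1 segment=V chain=TRG
ACTCGATACTGTGTTGTGGGTAATCTGACTAAAGCGTGCTGAACATGTAACACACCGCCT
>TRGV2 segment=V chain=TRG
ACTCCACTCTGTAGGTTTCCTCACAGCGAGCAGAGATGCTCCACATGTCCCAGATTCAAC
>TRGV3 segment=V chain=TRG
GTAAGCATACGGAACACCCTCCTGCGAAAGAAATCTTGCCCCGGGTGTGTACCTTCAGAC
>TRGV4 segment=V chain=TRG
GCCAAGCGGTCACCATATATACAACTCCTTCGACAACCGTAAGAGTGTGGCAGAGATCAG
>TRGV5 segment=V chain=TRG
CCCACAGATTGCCTAGTGCATGAGACTGATCTTCTTCGAGAGTCATGTCTCCTCGGGAAT
>TRGV6 segment=V chain=TRG
TATCGCTTATTATTTAGGCAGTATTACCAGTTAGGCTGTAATGACTGTTGGAGCTTTCGC
>TRGV7 segment=V chain=TRG
TACCGACATTAGGGCCAGACTGCTTTGCGCTCTGAATCTACTGAGTGTCAAGGGCAAACC
>TRGV8 segment=V chain=TRG
GAAGGGCCCCTTAGCCTGTCAGAGACATAAACCAGAGACAGACGATGTCCTCATCCTGGC
>TRGV9 segment=V chain=TRG
TACATTCAGCAAGGATACTTCAACTTTACCAACTCTTTATCTAGTTGTTCGGGCCCTCAG
>TRGV10 segment=V chain=TRG
GTGGGGCTGCACGTCTAACGGGCATCCGCGTAGCATCTTTGCGCATGTGCTCGTACCGCT
>TRGJ1 segment=J chain=TRG
GGAATTGTCATAAGACTGTTACTATTGGTTTCGACGAAGTAAGGG
>TRGJ2 segment=J chain=TRG
CGAACTGAATGGCTAATGGAGAAGACAGTTGTTGGTTCGTGAGAA
>TRGJ3 segment=J chain=TRG
TATAACGCGCGGGTGGACTTTATTGGTTATCCAGATAAATCATGC
>TRGJ4 segment=J chain=TRG
TTCTGTCACTCTCGGGAAGTGGTTGCGATAATGACCTATTTAAAA
>TRGJ5 segment=J chain=TRG
TGCCTCTGTCACGTGGTTGAGAGGCTCTAAGTTGCTAATAGAGGA
>TRDV1 segment=V chain=TRD
CCGTTTTGAGGTTGTTCAGGAAACAACTGACCAATTAAGCAGAGATGTGTTCGATGCAGA
>TRDV2 segment=V chain=TRD
CAGGAGAGGAAAGGAAGGCGTAACAATACGTGGGGCTCCTTTTAATGTTTCCACCATGCA
>TRDV3 segment=V chain=TRD
AGAATCAGTATCGAATGCCAATTGCCTTATTGCATCCGCCAGACGTGTAGTCTCCTGTAC
>TRDV4 segment=V chain=TRD
TCAGCTTCCACGAGCCACACTTTTTAAGCGTAAGTGCCGAAATTGTGTGAGTTGTTGTCT
>TRDV5 segment=V chain=TRD
GGTTTGCCTAATATCTCAAAGAAAGCAACATTGGGTGTTTGTAGGTGTCGTTGTGGGGTG
>TRDV6 segment=V chain=TRD
CGAAGAGAGATTCCCTATACACAAAAGCCCATTTCGGTTGCTGGCTGTACCCTAGCGAAC
>TRDV7 segment=V chain=TRD
AACCGATATGTTAAAAGACCTGCACGCTGGAGAGCATTACTCCGTTGTATAGCTTCGATG
>TRDV8 segment=V chain=TRD
ATAGTAGTGCGTTTGTCGTCCAGACGGGACGGTGTTATCACCGAGTGTGAGCTCTTGGGG
>TRDV9 segment=V chain=TRD
CTTTCACTAACCGCCGGAGCAGTTGGCCGAGGGGGCCTGAGATCATGTAATGGAATTATG
>TRDV10 segment=V chain=TRD
TGGGCTGGGGACTACAAATCAGGCGAACTACTTGAAGAGGCTCCCTGTGTCATTGGGGCA
>TRDJ1 segment=J chain=TRD
CATGAGACTCGTAAATGTATAAGTATGCAACTCCGCAACATACAG
>TRDJ2 segment=J chain=TRD
GAAAGGGGAATGCAAAGTGAGTAACCGGCGCGGCGAAGGGGGGAA
>TRDJ3 segment=J chain=TRD
CCTCGGTATACGCGCTCACTGCCCTAAAAGCTACAGAACTTGTAC
>TRDJ4 segment=J chain=TRD
TCAATATTACCTAAGACAAGCTGCCTTGGTCAGAGTCAACCTTCG
>TRDJ5 segment=J chain=TRD
AGTTGCACTAGTGCATAGCCAAGAGAACATAAAACGCATCGCTTC
>TRBD1 segment=D chain=TRB
CGGAAGTCCACTCA
>TRBD2 segment=D chain=TRB
TTACCGCAGTCAAG
>TRDD1 segment=D chain=TRD
GATGCCTTTCCGTT
>TRDD2 segment=D chain=TRD
TTCCGCCGTATAGC
>TRDD3 segment=D chain=TRD
AGAGCTTCACGCGG
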