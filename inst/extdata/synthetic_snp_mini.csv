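AlleleID,CloneID,AlleleSequence,TrimmedSequence,SNP,SnpPosition,CallRate,OneRatioRef,OneRatioSnp,FreqHomRef,FreqHomSnp,FreqHets,PICRef,PICSnp,AvgPIC,AvgCountRef,AvgCountSnp,RepAvg,C1_M01,C1_M02,C1_M03,C1_M04,C1_F01,C1_F02,C1_F03,C1_F04
SNPAUT_00001,SNPAUT_00001,AAGCCCGATACCTTTGCTAATATTTTTAACATGTAAGGTTTCACCGACAGTACACTGCAGTCAT,AAGCCCGATACCTTTGCTAATATTTTTAACATGTAAGGTTTCACCGACAGTACACTGCAGTCAT,62:A>C,62,1,0.375,1,0,0.625,0.375,0.46875,0,0.3046875,49.4,38.5,1,1,1,1,1,2,2,1,2
SNPAUT_00002,SNPAUT_00002,GTGCGCCAAGAGTCCTGTGCTGAGAATAGGTATTAGTCAGTCGATTAGACTGTCACGTTCTATC,GTGCGCCAAGAGTCCTGTGCTGAGAATAGGTATTAGTCAGTCGATTAGACTGTCACGTTCTATC,8:A>T,8,0.75,0.16666666666666666,1,0,0.8333333333333334,0.16666666666666666,0.2777777777777777,0,0.1527777777777779,12,33.9,1,-,1,1,-,1,2,1,1
SNPAUT_00003,SNPAUT_00003,TAGTCGTAAACGTTTTGCGTAGCCGAGTTTATATCAAAGCCTTGACAATCAGAAGCTGGTTGAC,TAGTCGTAAACGTTTTGCGTAGCCGAGTTTATATCAAAGCCTTGACAATCAGAAGCTGGTTGAC,25:A>C,25,0.875,0.8571428571428571,0.2857142857142857,0.7142857142857143,0.14285714285714285,0.14285714285714285,0.24489795918367352,0.40816326530612246,0.33673469387755106,55.5,49.3,1,0,0,0,0,2,1,0,-
SNPAUT_00004,SNPAUT_00004,TGGCGCTCTCGCCACTACGGGCTTACGGGAGCCAACAATTGACCAGATCTTCTACCACTTATAT,TGGCGCTCTCGCCACTACGGGCTTACGGGAGCCAACAATTGACCAGATCTTCTACCACTTATAT,31:C>A,31,1,0.875,0.75,0.25,0.125,0.625,0.21875,0.375,0.4921875,44.8,29.8,1,2,2,0,1,2,2,2,0
SNPAUT_00005,SNPAUT_00005,ATTTATATTCAGCGTGGCAATCTTTCCAAGGCGTTCGGTAGACGGCTTTGGAAGTCTCTCAGGT,ATTTATATTCAGCGTGGCAATCTTTCCAAGGCGTTCGGTAGACGGCTTTGGAAGTCTCTCAGGT,40:G>A,40,1,0,1,0,1,0,0,0,0,39.8,8.9,1,1,1,1,1,1,1,1,1
SNPAUT_00006,SNPAUT_00006,CCCGTGATCTGATCGCCGTTCAAGCTAAGGAAAGTAGATTGTTAACTTTGAGTATTCCCGCTCT,CCCGTGATCTGATCGCCGTTCAAGCTAAGGAAAGTAGATTGTTAACTTTGAGTATTCCCGCTCT,40:G>C,40,0.875,0,1,0,1,0,0,0,0,39.3,8.7,1,1,1,1,1,1,1,1,-
SNPSEX_00001,SNPSEX_00001,GTGGTGGGACGTTACACATCGTAAATCCCGATGCTAGGGGATCCTACCGTGTGCGCGGGAATAT,GTGGTGGGACGTTACACATCGTAAATCCCGATGCTAGGGGATCCTACCGTGTGCGCGGGAATAT,19:C>A,19,0.875,0.42857142857142855,1,0,0.5714285714285714,0.42857142857142855,0.48979591836734704,0,0.33673469387755106,47,52.7,1,-,2,2,2,1,1,1,1
SNPSEX_00002,SNPSEX_00002,GATCAATGTCGTAGCTCCGGAATTAGCGGTGACCAGCTTCACTAAGCCGGATGGATCCTCTGCG,GATCAATGTCGTAGCTCCGGAATTAGCGGTGACCAGCTTCACTAAGCCGGATGGATCCTCTGCG,13:G>C,13,1,0.5,1,0,0.5,0.5,0.5,0,0.375,27.8,13.7,1,2,2,2,2,1,1,1,1
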