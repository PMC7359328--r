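guide_id	spacer	gene	domain	category
Epi01_cr1	CCTGAATCGTGTATAAGGCGCGC	Epi01	Epi01_dom	domain
Epi01_cr2	TAGTACCCGGCCCCTTAGTTCTA	Epi01	Epi01_dom	domain
Epi01_cr3	GGACGTACCCCACAGAGCTCCAC	Epi01	Epi01_dom	domain
Epi02_cr1	CGCCTGAAACTGTATGCTGGCCC	Epi02	Epi02_dom	domain
Epi02_cr2	CTCCTCCCTGCGTACGTTGGGTG	Epi02	Epi02_dom	domain
Epi02_cr3	CTAGATGATAGCGGATGATTCGA	Epi02	Epi02_dom	domain
Epi03_cr1	GACGGAGGTGGATTTGGCAATTT	Epi03	Epi03_dom	domain
Epi03_cr2	CAGTTCGGTACTCAAGATATCAT	Epi03	Epi03_dom	domain
Epi03_cr3	TTCTTCTGACCCTAAGGGCAACA	Epi03	Epi03_dom	domain
Epi04_cr1	CTGTGGGGAGCGTTATCGGGCTA	Epi04	Epi04_dom	domain
Epi04_cr2	CTACACTTGGCCTGGTACTCTCC	Epi04	Epi04_dom	domain
Epi04_cr3	GTGGCCTCACGAGGACGCTTACT	Epi04	Epi04_dom	domain
Epi05_cr1	GCGCCGATCCGCCTTACTTCACC	Epi05	Epi05_dom	domain
Epi05_cr2	ATGCCTCTATCGAGCCTATCTGA	Epi05	Epi05_dom	domain
Epi05_cr3	TTGACACTGCCGACCATTGGCAA	Epi05	Epi05_dom	domain
Epi06_cr1	AAGCCTAGGATATGTAATACGTA	Epi06	Epi06_dom	domain
Epi06_cr2	GCCCGGGCCAACCGAAGTTAAGT	Epi06	Epi06_dom	domain
Epi06_cr3	CTCAGACCCACGATACCTTGGGG	Epi06	Epi06_dom	domain
Epi07_cr1	ATTGTATTATCAAATCCAATTCT	Epi07	Epi07_dom	domain
Epi07_cr2	CGTACAACTCTTTGCCTTCTCGG	Epi07	Epi07_dom	domain
Epi07_cr3	TCCTGAAATACAGTTCTGTACTT	Epi07	Epi07_dom	domain
Epi08_cr1	CATGTACCGTAGAGTCATTATGT	Epi08	Epi08_dom	domain
Epi08_cr2	ACAACTTTCTTAGCGTGGTCACA	Epi08	Epi08_dom	domain
Epi08_cr3	ACCTAGAGGGGCGTAGGAATTTC	Epi08	Epi08_dom	domain
Epi09_cr1	AACGTGAAGCAATTGGACCCATG	Epi09	Epi09_dom	domain
Epi09_cr2	AAGGTACGGAAGGGACGCTGTGT	Epi09	Epi09_dom	domain
Epi09_cr3	CATAGTGATAAGAAAATAACACA	Epi09	Epi09_dom	domain
Epi10_cr1	CGCAGACGTGTCCTTTAAGCGTG	Epi10	Epi10_dom	domain
Epi10_cr2	AGCGGAGACCTCGGCTCTGTACA	Epi10	Epi10_dom	domain
Epi10_cr3	GAGTGCCTGTGAGTTAAGACGTA	Epi10	Epi10_dom	domain
Epi11_cr1	TATCGCGGACAAGCCATTCATTA	Epi11	Epi11_dom	domain
Epi11_cr2	CACTGTGTAAGGCTCACAGGTAT	Epi11	Epi11_dom	domain
Epi11_cr3	AGGACGGTTTACCATGGATTCAA	Epi11	Epi11_dom	domain
Epi12_cr1	CGTAGAATTCGGTCGAAGACAAT	Epi12	Epi12_dom	domain
Epi12_cr2	TCGCCCTTAATGTCTACGCTTGC	Epi12	Epi12_dom	domain
Epi12_cr3	CGGGGAACCCTATCTAACACACA	Epi12	Epi12_dom	domain
Epi13_cr1	AAAGCCCTGCAGATTTAATCACC	Epi13	Epi13_dom	domain
Epi13_cr2	TTTGCAAAACCTAGAGGATAGTA	Epi13	Epi13_dom	domain
Epi13_cr3	AGTTGCCATTAGGCTTACTGATA	Epi13	Epi13_dom	domain
Epi14_cr1	TGCAGCGGGGGGATAGTCAGCTT	Epi14	Epi14_dom	domain
Epi14_cr2	GGGGATACTAGATTACAGGAGGA	Epi14	Epi14_dom	domain
Epi14_cr3	TAAGTCAAGGCCAGGTAAGCAAC	Epi14	Epi14_dom	domain
Epi15_cr1	TATAAGCCATCTTGAACTTACCT	Epi15	Epi15_dom	domain
Epi15_cr2	GGTTGCACAGGCGCAGTGATTAC	Epi15	Epi15_dom	domain
Epi15_cr3	ATGACATCTCCGTACTCAATTTA	Epi15	Epi15_dom	domain
Epi16_cr1	TGCCTTTGTTGTCTACATAAATA	Epi16	Epi16_dom	domain
Epi16_cr2	CTTCCGTTTCCTTTTCGTGGATT	Epi16	Epi16_dom	domain
Epi16_cr3	TGTTCTTGTGTAAAGGCCAGCCC	Epi16	Epi16_dom	domain
Epi16_cr4	GTTAACATGATCCTTCTGGTACG	Epi16	Epi16_dom	domain
Epi17_cr1	GATTGGAGAATTGTAAGCCATCT	Epi17	Epi17_dom	domain
Epi17_cr2	GCCTATCTAGGTAGGTACGGTTA	Epi17	Epi17_dom	domain
Epi17_cr3	TTTGGCCATGTGCCTTATGGTTC	Epi17	Epi17_dom	domain
Epi17_cr4	CAGCGGATTTGTCAGGGGCGCGG	Epi17	Epi17_dom	domain
Epi18_cr1	GATATCATTGCGCTACTCAGCCC	Epi18	Epi18_dom	domain
Epi18_cr2	GGTGCGCCCATATATCCTCCATT	Epi18	Epi18_dom	domain
Epi18_cr3	TAAAAAGACAATTAGCGACAACA	Epi18	Epi18_dom	domain
Epi18_cr4	ACTTTCCAATAATAATGCTGCGG	Epi18	Epi18_dom	domain
Epi19_cr1	AAAGCGGAATGTAAAGATAAATA	Epi19	Epi19_dom	domain
Epi19_cr2	GGATATTACACGGCACCCAAGCC	Epi19	Epi19_dom	domain
Epi19_cr3	TTAATTCTAAACGACTACTGCGC	Epi19	Epi19_dom	domain
Epi19_cr4	AGACGTCCTTCCTGGCGAGAATG	Epi19	Epi19_dom	domain
Epi20_cr1	TGCTGTTCCGCGATCTATTGCCC	Epi20	Epi20_dom	domain
Epi20_cr2	CCGCTCGGATCGCAAGTGCGGCC	Epi20	Epi20_dom	domain
Epi20_cr3	TTTCATGAAGTGAACAAAGGCGC	Epi20	Epi20_dom	domain
Epi20_cr4	CTTATAAAAGTCAAGATCACCGG	Epi20	Epi20_dom	domain
Epi21_cr1	TGTTCGCCCTTTGCGGGCTGAAA	Epi21	Epi21_dom	domain
Epi21_cr2	GATGTGGCACTTGCCGTCCGGCG	Epi21	Epi21_dom	domain
Epi21_cr3	GCTAGCGAAAACGGGCTCCGATC	Epi21	Epi21_dom	domain
Epi21_cr4	TCGTCCCAACAGGCCAGAGACTT	Epi21	Epi21_dom	domain
negctrl01	GGTATAAGCGATGTCGCAAATCT	neg_ctrl	NA	negative_control
negctrl02	CGGTAGGCGGTTTTTTGGAAGTC	neg_ctrl	NA	negative_control
negctrl03	GATCGCTAGTAGGGCCGGACGGA	neg_ctrl	NA	negative_control
negctrl04	CATACGTCTAACAGGGCCTCTAA	neg_ctrl	NA	negative_control
negctrl05	CACCGTATACAAACCTTAGCGCG	neg_ctrl	NA	negative_control
negctrl06	ACGACGCGGGAATCATTTTTTAT	neg_ctrl	NA	negative_control
negctrl07	TTAGACCCCTCGTCTAAATCACC	neg_ctrl	NA	negative_control
negctrl08	TGACATCATGTAGAAATCCTAAT	neg_ctrl	NA	negative_control
negctrl09	CCACTGCCTTGCTACCCTCCCAA	neg_ctrl	NA	negative_control
negctrl10	GGGCGCTTTGGGGAGGATGCCCC	neg_ctrl	NA	negative_control
negctrl11	AAGTTGATTGAAGTGTCCATGTC	neg_ctrl	NA	negative_control
negctrl12	GCACCTTAACCTGGTGGCAGGAA	neg_ctrl	NA	negative_control
negctrl13	CGCGCTCCGGCATTTCGTTGGTG	neg_ctrl	NA	negative_control
negctrl14	CAGTATACTTACGACTGGACATG	neg_ctrl	NA	negative_control
negctrl15	TCTAGGAACACGGTCTTTGGCCC	neg_ctrl	NA	negative_control
negctrl16	GTACCACACACAACCATTGATAA	neg_ctrl	NA	negative_control
negctrl17	CTGCCCACCCCTATCATCTATGA	neg_ctrl	NA	negative_control
negctrl18	CATGCTCTTCAAAAATTGACGAC	neg_ctrl	NA	negative_control
negctrl19	GGACCTATATTTCAGGGATAACC	neg_ctrl	NA	negative_control
negctrl20	CTTCAGGCGTCACTACTCATATG	neg_ctrl	NA	negative_control
negctrl21	CCTACTCGGCTGCACGCTATAGT	neg_ctrl	NA	negative_control
negctrl22	CCGCGGTCCGGTAACCTGATCGG	neg_ctrl	NA	negative_control
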