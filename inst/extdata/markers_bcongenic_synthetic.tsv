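name	chrom	pos_mb	donor_hap	recipient_hap	congenic_hap
Fkrp	chr7	30.90	ACGTACGT	ACCTACAT	ACGTACGT
Plaur	chr7	31.40	TTGCAGCA	TTGCGGCA	TTGCAGCA
Aplp1	chr7	32.10	GGATCCTA	GGGTCCTA	GGATCCTA
Abpa2	chr7	32.30	CAGTTAGC	CAATTAGC	CAGTTAGC
Abpa21p	chr7	33.20	TGCATGCA	TGCATACA	TGCATGCA
Abpa24	chr7	33.60	ATCGGATC	ATCAGATC	ATCGGATC
Abpbg27	chr7	34.73	GCTAGCTA	GCTAACTA	GCTAGCTA
Abpbg26	chr7	34.80	CGATCGAT	CGATCAAT	CGATCGAT
Abpa27	chr7	34.81	TACGTACG	TACGTGCG	TACGTACG
Abpa30p	chr7	34.90	GATCGATC	GATCAATC	GATCGATC
Lrp3	chr7	35.90	CCGGAATT	CCAGAATT	CCGGAATT
Ccne1	chr7	38.80	AATTCCGG	AATTCCAG	AATTCCGG
Siglece	chr7	50.90	GGCCTTAA	GACCTTAA	GACCTTAA
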