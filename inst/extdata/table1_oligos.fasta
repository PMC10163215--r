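>probe_DNA_1 role=probe orientation=5to3 variant=5370C>T mutation_bearing=FALSE thiol=TRUE
AGGTCCAAAGCGAGCAAGAGAAGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_1 role=target orientation=3to5 variant=5370C>T mutation_bearing=FALSE thiol=FALSE
TCCAGGTTTCGCTCGTTCTCTTCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_2 role=probe orientation=5to3 variant=5370C>T mutation_bearing=TRUE thiol=TRUE
AGGTCCAAAGTGAGCAAGAGAAGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_2 role=target orientation=3to5 variant=5370C>T mutation_bearing=TRUE thiol=FALSE
TCCAGGTTTCACTCGTTCTCTTCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_3 role=probe orientation=5to3 variant=5382insC mutation_bearing=FALSE thiol=TRUE
AAGAGAATCCC-AGGACAGAAAGGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_3 role=target orientation=3to5 variant=5382insC mutation_bearing=FALSE thiol=FALSE
TTCTCTTAGGG-TCCTGTCTTTCCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_4 role=probe orientation=5to3 variant=5382insC mutation_bearing=TRUE thiol=TRUE
AAGAGAATCCCCAGGACAGAAAGGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_4 role=target orientation=3to5 variant=5382insC mutation_bearing=TRUE thiol=FALSE
TTCTCTTAGGGGTCCTGTCTTTCCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_5 role=probe orientation=5to3 variant=c.4035delA mutation_bearing=FALSE thiol=TRUE
TCAGATGATGAAGAAAGAGGAACGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_5 role=target orientation=3to5 variant=c.4035delA mutation_bearing=FALSE thiol=FALSE
AGTCTACTACTTCTTTCTCCTTGCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_6 role=probe orientation=5to3 variant=c.4035delA mutation_bearing=TRUE thiol=TRUE
TCAGATGATGA-GAAAGAGGAACGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_6 role=target orientation=3to5 variant=c.4035delA mutation_bearing=TRUE thiol=FALSE
AGTCTACTACT-CTTTCTCCTTGCCTCACCCAGGGTAGTCAAACTT
>probe_DNA_7 role=probe orientation=5to3 variant=185delAG mutation_bearing=FALSE thiol=TRUE
CAGAAAATCTTAGAGTGTCCCATGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_7 role=target orientation=3to5 variant=185delAG mutation_bearing=FALSE thiol=FALSE
GTCTTTTAGAATCTCACAGGGTACCTCACCCAGGGTAGTCAAACTT
>probe_DNA_8 role=probe orientation=5to3 variant=185delAG mutation_bearing=TRUE thiol=TRUE
CAGAAAATCTTAG--TGTCCCATGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_8 role=target orientation=3to5 variant=185delAG mutation_bearing=TRUE thiol=FALSE
GTCTTTTAGAATC--ACAGGGTACCTCACCCAGGGTAGTCAAACTT
>probe_DNA_9 role=probe orientation=5to3 variant=3819del5GTAAA mutation_bearing=FALSE thiol=TRUE
ATTTGGTAAAGTAAACAATATACCTGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_9 role=target orientation=3to5 variant=3819del5GTAAA mutation_bearing=FALSE thiol=FALSE
TAAACCATTTCATTTGTTATATGGACCTCACCCAGGGTAGTCAAACTT
>probe_DNA_10 role=probe orientation=5to3 variant=3819del5GTAAA mutation_bearing=TRUE thiol=TRUE
ATTTGGTAAA-----CAATATACCTGGAGTGGGTCCCATCAGTTTGAA
>target_DNA_10 role=target orientation=3to5 variant=3819del5GTAAA mutation_bearing=TRUE thiol=FALSE
TAAACCATTT-----GTTATATGGACCTCACCCAGGGTAGTCAAACTT
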