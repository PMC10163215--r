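panel,sample_id,sample_uid,status,qcmd_call,spr_call,pcr_call
5370C>T,5417/21,P-5417/21,mutation,ambiguous,positive,positive
5370C>T,5297/21,N-5297/21,without_mutation,negative,negative,negative
5370C>T,5623/21,N-5623/21,without_mutation,negative,negative,negative
5370C>T,5528/21,N-5528/21,without_mutation,negative,negative,negative
5370C>T,5577/21,N-5577/21,without_mutation,negative,negative,negative
5370C>T,5615/21,N-5615/21,without_mutation,negative,negative,negative
5382insC,5675/21,P-5675/21,mutation,positive,positive,positive
5382insC,5398/21,P-5398/21,mutation,positive,positive,positive
5382insC,2225/21,P-2225/21,mutation,positive,positive,positive
5382insC,5714/21,P-5714/21,mutation,positive,positive,positive
5382insC,5675/21,P-5675/21b,mutation,positive,positive,positive
5382insC,5252/21,P-5252/21,mutation,positive,positive,positive
5382insC,5187/21,P-5187/21,mutation,positive,positive,positive
5382insC,4937/21,P-4937/21,mutation,positive,positive,positive
5382insC,4930/21,P-4930/21,mutation,positive,positive,positive
5382insC,4928/21,P-4928/21,mutation,positive,positive,positive
5382insC,5297/21,N-5297/21,without_mutation,negative,negative,negative
5382insC,5623/21,N-5623/21,without_mutation,ambiguous,negative,negative
5382insC,5528/21,N-5528/21,without_mutation,negative,negative,negative
5382insC,5577/21,N-5577/21,without_mutation,negative,negative,negative
5382insC,5615/21,N-5615/21,without_mutation,negative,negative,negative
c.4035delA,1848/21,P-1848/21,mutation,positive,positive,positive
c.4035delA,2942/21,P-2942/21,mutation,positive,positive,positive
c.4035delA,5297/21,N-5297/21,without_mutation,negative,negative,negative
c.4035delA,5623/21,N-5623/21,without_mutation,negative,negative,negative
c.4035delA,5528/21,N-5528/21,without_mutation,negative,negative,negative
c.4035delA,5577/21,N-5577/21,without_mutation,negative,negative,negative
c.4035delA,5615/21,N-5615/21,without_mutation,negative,negative,negative
185delAG,2342,P-2342,mutation,positive,positive,positive
185delAG,5297/21,N-5297/21,without_mutation,negative,negative,negative
185delAG,5623/21,N-5623/21,without_mutation,negative,negative,negative
185delAG,5528/21,N-5528/21,without_mutation,negative,negative,negative
185delAG,5577/21,N-5577/21,without_mutation,negative,negative,negative
185delAG,5615/21,N-5615/21,without_mutation,negative,negative,negative
3819del5GTAAA,1606/21,P-1606/21,mutation,positive,positive,positive
3819del5GTAAA,899/21,P-899/21,mutation,positive,positive,positive
3819del5GTAAA,901/21,P-901/21,mutation,positive,positive,positive
3819del5GTAAA,5297/21,N-5297/21,without_mutation,negative,negative,negative
3819del5GTAAA,5623/21,N-5623/21,without_mutation,negative,negative,negative
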