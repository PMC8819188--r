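track name=recursive_splice_sites description="catalogued RSS boundary bases (0-based)"
chr11	108287437	108287438	ATM_RSS
chrX	108570794	108570795	COL4A5_RSS
chr5	148411079	148411080	FBOX38_RSS
chrX	101401346	101401347	GLA_RSS
chr5	71636103	71636104	MCCC2_RSS
chr3	132717954	132717955	NPHP3_RSS
chrX	129553235	129553236	OCRL_RSS
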