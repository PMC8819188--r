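#pe_id	gene	transcript	chrom	strand	intron_index	pe_start	pe_end	acceptor_dinuc	donor_dinuc	mutations	splice_evidence_acceptor	splice_evidence_donor	is_terminal	polya_confirmed	frame_preserving	category	cell_types	citations
ATM-27-1b	ATM		chr11	+	27	108287409	108287521	AG	GT	c.3994-159A>G	1	0	0	0	0
ATM-27-1a	ATM		chr11	+	27	108287409	108287438	AG	GT	c.3994-193C>T	1	0	0	0	0
COL4A5-6-1	COL4A5		chrX	+	6	108570648	108570795	AG	GT	c.385-719G>A	1	0	0	0	1
FBOX38-9-1	FBOX38		chr5	+	9	148411079	148411238	AG	GT	c.1093+532C>G	1	0	0	0	1
GLA-3-1	GLA		chrX	-	3	101401232	101401347	AG	GT	c.547+395G>C	1	0	0	0	0
MCCC2-10-1	MCCC2		chr5	+	10	71636103	71636167	AG	GT	c.1054G>A	1	0	0	0	0
NPHP3-3-1	NPHP3		chr3	-	3	132717954	132718117	AG	GT	c.671-996C>G	1	0	0	0	0
OCRL-4-1	OCRL		chrX	+	4	129553235	129553301	AG	GT	c.239-4023A>G	1	0	0	0	1
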