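# Pseudoexons with normal-tissue splice evidence assessed against recursive
# splice sites (RSS). Coordinates are 0-based half-open on the reference
# strand. rss_side names the pseudoexon boundary that coincides with a
# catalogued RSS ("none" when neither does). MaxEnt-style acceptor/donor
# scores are given before -> after the instigating mutation (equal when the
# mutation leaves that site unchanged).
#pe_id	gene	chrom	strand	pe_start	pe_end	size	mutation	position_label	me_acceptor_before	me_acceptor_after	me_donor_before	me_donor_after	rss_side
ATM-27-1b	ATM	chr11	+	108287409	108287521	112	c.3994-159A>G	A+32	7.71	8.12	8.49	8.49	none
ATM-27-1a	ATM	chr11	+	108287409	108287438	29	c.3994-193C>T	A-3	NA	NA	6.38	6.38	donor
COL4A5-6-1	COL4A5	chrX	+	108570648	108570795	147	c.385-719G>A	A+46	5.25	5.25	7.51	7.51	donor
FBOX38-9-1	FBOX38	chr5	+	148411079	148411238	159	c.1093+532C>G	D+59	9.11	9.11	6.57	6.57	acceptor
GLA-3-1	GLA	chrX	-	101401232	101401347	115	c.547+395G>C	D-5	5.10	5.10	7.82	7.82	acceptor
MCCC2-10-1	MCCC2	chr5	+	71636103	71636167	64	c.1054G>A	e11 D-19	5.72	5.72	3.24	3.24	acceptor
NPHP3-3-1	NPHP3	chr3	-	132717954	132718117	163	c.671-996C>G	D+50	6.50	6.50	0.56	0.56	donor
OCRL-4-1	OCRL	chrX	+	129553235	129553301	66	c.239-4023A>G	D+1	8.18	8.18	2.68	10.86	acceptor
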