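gene	boundary	position	evidence
COL4A3	exon_end	144	intronic variant c.144+12
COL4A3	exon_start	547	intronic variant c.547-9
COL4A3	exon_end	687	stated exon boundary (exon-terminal splice-region change at c.687)
COL4A3	exon_end	765	splice-donor variant c.765+2
COL4A3	exon_start	2384	intronic variant c.2384-5
COL4A4	exon_start	1100	splice-acceptor variant c.1100-2
COL4A4	exon_end	1369	deletion span end c.1369+2
COL4A4	exon_start	2717	intronic variant c.2717-5
COL4A4	exon_end	3817	intronic variant c.3817+9
COL4A5	exon_start	82	first exonic base; substitution disrupts the acceptor consensus
COL4A5	exon_start	1033	intronic variant c.1033-6
COL4A5	exon_start	1780	splice-acceptor variant c.1780-1
COL4A5	exon_end	2395	splice-donor variant c.2395+1
COL4A5	exon_start	2768	intronic variant c.2768-11
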