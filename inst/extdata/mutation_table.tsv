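gene	cdna	protein	consequence_label	published_status	source	in_controls	segregation	cases
COL4A3	c.687G>A	NA	splice region	none	NA	FALSE	consistent	F4
COL4A3	c.3490G>T	p.Gly1164Cys	missense	none	NA	FALSE	consistent	F4
COL4A3	c.765+2T>C	NA	splice donor	none	NA	FALSE	consistent	F12
COL4A3	c.3410G>A	p.Gly1137Asp	missense	none	NA	FALSE	consistent	F13
COL4A3	c.765G>T	NA	splice region	none	NA	FALSE	consistent	F2
COL4A4	c.2320G>C	p.Gly774Arg	missense	pathogenic	literature	FALSE	consistent	F3
COL4A4	c.2986G>A	p.Gly996Arg	missense	none	NA	FALSE	NA	I3
COL4A4	c.1100-2A>C	NA	splice acceptor	none	NA	FALSE	consistent	F8
COL4A4	c.1320_1369+2del	NA	deletion, splice donor	none	NA	FALSE	consistent	F3
COL4A5	c.1780-1G>T	NA	splice acceptor	none	NA	FALSE	consistent	F9
COL4A5	c.1871G>A	p.Gly624Asp	missense	pathogenic	literature	FALSE	consistent	F10;F14;I2
COL4A5	c.1033-6A>G	NA	presumed splice variant	none	NA	FALSE	consistent	F7
COL4A5	c.2395+1G>A	NA	splice donor	none	NA	FALSE	consistent	F5
COL4A5	c.1094G>A	p.Gly365Glu	missense	pathogenic	literature	FALSE	consistent	F1
COL4A5	c.2741G>A	p.Gly914Asp	missense	none	NA	FALSE	consistent	F6
COL4A5	c.82G>T	p.Ala28Ser	missense, splice acceptor	none	NA	FALSE	consistent	F11
COL4A5	c.1010G>T	p.Gly337Val	missense	none	NA	FALSE	NA	I1
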