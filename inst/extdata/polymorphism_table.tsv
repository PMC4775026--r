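gene	cdna	maf	protein	consequence_label	published_status	source	in_controls	note	cases
COL4A3	c.127G>C	0.153	p.Gly43Arg	missense	polymorphism	literature	TRUE	NA	F1;F5;F6;F10;F13
COL4A3	c.1721C>T	0.121	p.Pro574Leu	missense	polymorphism	literature	TRUE	NA	F1;F5;F2;F4;F8;F10;F11;F12;F13;F14;I1;I2
COL4A3	c.3325C>T	0.024	p.Pro1109Ser	missense	polymorphism	literature	TRUE	NA	F4
COL4A3	c.547-9A>C	0.024	NA	IV	polymorphism	rs55667591	TRUE	NA	F3;F4
COL4A3	c.3807C>A	0.040	p.Asp1269Glu	missense	polymorphism	literature	TRUE	NA	F2;F6
COL4A3	c.976G>T	0.226	p.Asp326Tyr	missense	polymorphism	literature	TRUE	NA	F3;F6;I3;F7;F13;F11;F8
COL4A3	c.2384-5T>C	0.113	NA	IV	polymorphism	literature	TRUE	NA	F10;F7
COL4A3	c.485A>G	0.798	p.Glu162Gly	missense	polymorphism	literature	TRUE	NA	F1;F2;F3;F4;F5;F6;F7;F8;F9;F10;F11;F12;F13;I1;I2;I3
COL4A3	c.144+12C>A	0.339	NA	IV	polymorphism	literature	TRUE	NA	F3;F6;F8;F9;F10;F11;F13;I1;I2;I3
COL4A3	c.422T>C	0.798	p.Leu141Pro	missense	polymorphism	literature	TRUE	NA	F1;F2;F3;F4;F5;F6;F7;F8;F9;F10;F11;F12;F13;I1;I2;I3
COL4A3	c.1352A>G	0.105	p.His451Arg	missense	polymorphism	literature	TRUE	NA	I2;F9
COL4A4	c.2717-5A>T	0.040	NA	IV	polymorphism	literature	TRUE	NA	F11
COL4A4	c.2501A>G	0.008	p.Lys834Arg	missense	polymorphism	literature	TRUE	NA	F11
COL4A4	c.4207T>C	0.355	p.Ser1403Pro	missense	polymorphism	literature	TRUE	NA	F2;F3;F4;F5;F6;F7;F10;F12;I1;I2
COL4A4	c.3817+9G>C	0.363	NA	IV	polymorphism	literature	TRUE	NA	F1;F10;F4;F7;F13;I3
COL4A4	c.3979G>A	0.363	p.Val1327Met	missense	polymorphism	literature	TRUE	NA	F1;F10;F4;F12;F7;F13;I3
COL4A4	c.1444C>T	0.435	p.Pro482Ser	missense	polymorphism	literature	TRUE	NA	F1;F2;F3;F5;F6;F7;F10;F11;F12;F13;I1;I2
COL4A4	c.3011C>T	0.444	p.Pro1004Leu	missense	polymorphism	literature	TRUE	NA	F1;F2;F3;F4;F5;F6;F7;F10;F12;F13;I1;I2;I3
COL4A4	c.2996G>A	0.008	p.Gly999Glu	missense	polymorphism	literature	TRUE	rare variant of uncertain effect: also observed in one young control whose later FBH manifestation could not be excluded	F4
COL4A4	c.4394G>A	NA	p.Gly1465Asp	missense	polymorphism	literature	TRUE	reported both as polymorphism and as pathogenic; co-occurs with the established pathogenic COL4A4:c.2320G>C in the same family, so its independent effect is unresolved	F3
COL4A5	c.2768-11A>G	0.065	NA	IV	polymorphism	literature	TRUE	NA	F3;I1;F10;I2;I3
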