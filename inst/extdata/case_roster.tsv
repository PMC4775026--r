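case_id	case_type	variant_keys
F1	family	COL4A5:c.1094G>A
F2	family	COL4A3:c.765G>T
F3	family	COL4A4:c.2320G>C;COL4A4:c.1320_1369+2del
F4	family	COL4A3:c.687G>A;COL4A3:c.3490G>T
F5	family	COL4A5:c.2395+1G>A
F6	family	COL4A5:c.2741G>A
F7	family	COL4A5:c.1033-6A>G
F8	family	COL4A4:c.1100-2A>C
F9	family	COL4A5:c.1780-1G>T
F10	family	COL4A5:c.1871G>A
F11	family	COL4A5:c.82G>T
F12	family	COL4A3:c.765+2T>C
F13	family	COL4A3:c.3410G>A
F14	family	COL4A5:c.1871G>A
I1	individual	COL4A5:c.1010G>T
I2	individual	COL4A5:c.1871G>A
I3	individual	COL4A4:c.2986G>A
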