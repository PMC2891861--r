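base	pos1	pos2	pos3	pos4	pos5	pos6	pos7	pos8	pos9	pos10	pos11
A	0.06	0.04	0.04	0.88	0.12	0.25	0.25	0.25	0.04	0.04	0.88
C	0.4400000000	0.0400000000	0.0400000000	0.0400000000	0.2933333333	0.2500000000	0.2500000000	0.2500000000	0.0400000000	0.8800000000	0.0400000000
G	0.4400000000	0.0400000000	0.8800000000	0.0400000000	0.2933333333	0.2500000000	0.2500000000	0.2500000000	0.8800000000	0.0400000000	0.0400000000
T	0.0600000000	0.8800000000	0.0400000000	0.0400000000	0.2933333333	0.2500000000	0.2500000000	0.2500000000	0.0400000000	0.0400000000	0.0400000000
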