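component,RSC1,RSC2,RSC3,RSC4,RSC5,RSC6,RSC7,RSC8,RSC9,RSC10
CP,a,de,abc,abc,ab,ab,e,cde,abcd,bcd
Arg,,,,,,,,,,
His,cd,cd,bc,d,d,cd,ab,a,a,ab
Ile,ab,bc,bc,ab,ab,a,ab,ab,a,c
Leu,ab,ab,ab,ab,a,a,a,bc,c,c
Lys,a,b,a,a,a,a,b,a,a,a
Met,b,bc,c,bc,c,bc,a,a,a,a
Phe,bc,bc,bc,c,bc,b,a,a,a,a
Thr,ab,b,ab,b,ab,ab,ab,ab,a,ab
Trp,,,,,,,,,,
Val,a,a,a,a,a,a,ab,a,a,c
Ala,ab,ab,ab,ab,ab,ab,b,ab,a,ab
Asp,,,,,,,,,,
Cys,bc,bc,abc,c,abc,c,ab,a,a,abc
Glu,ab,bc,abc,abc,abc,abc,c,abc,a,abc
Gly,a,cd,a,a,a,a,b,b,a,a
Pro,ab,a,a,abc,bc,bc,b,abc,a,ab
Ser,ab,b,ab,ab,ab,b,b,ab,a,a
Tyr,,,,,,,,,,
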