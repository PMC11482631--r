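component,RSC1,RSC2,RSC3,RSC4,RSC5,RSC6,RSC7,RSC8,RSC9,RSC10
CP,a,de,abc,abc,ab,ab,e,cde,bcd,cde
Arg,ab,ab,a,ab,ab,ab,ab,ab,ab,b
His,cd,cd,bc,d,d,cd,ab,a,a,ab
Ile,ab,d,cd,ab,bcd,a,abc,ab,ab,e
Leu,ab,ab,ab,ab,a,a,a,bc,c,c
Lys,a,b,a,a,a,a,b,a,a,a
Met,b,bc,c,bc,c,c,a,a,a,a
Phe,b,b,b,c,b,a,a,a,a,a
Thr,ab,ab,ab,b,ab,ab,ab,ab,a,ab
Trp,a,ab,c,abc,ab,ab,ab,a,bc,ab
Val,a,ab,ab,ab,a,ab,bc,a,a,c
Ala,ab,ab,ab,ab,ab,a,b,ab,a,ab
Asp,,,,,,,,,,
Cys,bc,bc,abc,c,abc,c,ab,a,a,bc
Glu,ab,bc,abc,bc,abc,abc,c,bc,a,abc
Gly,a,ab,ab,ab,ab,ab,c,c,b,b
Pro,a,ab,ab,a,b,ab,ab,a,a,ab
Ser,abc,cd,abc,bcd,abcd,cd,d,bcd,ab,a
Tyr,a,ab,ab,ab,a,a,ab,ab,ab,b
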