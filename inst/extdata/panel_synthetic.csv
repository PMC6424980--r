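label,bitstring,source
0P,0000000,text
3Pa,1000101,synthetic
3Pb,0100101,synthetic
3Pc,0010101,synthetic
3Pd,0001101,synthetic
3Pe,1110000,synthetic
3Pf,0000111,text
3Pg,0101100,synthetic
3Ph,1001010,synthetic
3Pi,0101001,synthetic
3Pj,1010010,synthetic
3Pk,0011010,synthetic
4P,0001111,synthetic
5P,1111100,synthetic
6P,0111111,synthetic
7P,1111111,text
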