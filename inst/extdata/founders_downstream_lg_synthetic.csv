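locus,allele,frequency
A112,1,0.512274022555461
A112,2,0.0975451954889078
A112,3,0.0975451954889078
A112,4,0.0975451954889078
A112,5,0.0975451954889078
A112,6,0.0975451954889078
A130,1,0.374248871612291
A130,2,0.0893930183411013
A130,3,0.0893930183411013
A130,4,0.0893930183411013
A130,5,0.0893930183411013
A130,6,0.0893930183411013
A130,7,0.0893930183411013
A130,8,0.0893930183411013
C4,1,0.464342851658196
C4,2,0.107131429668361
C4,3,0.107131429668361
C4,4,0.107131429668361
C4,5,0.107131429668361
C4,6,0.107131429668361
C114,1,0.702338622666273
C114,2,0.0595322754667454
C114,3,0.0595322754667454
C114,4,0.0595322754667454
C114,5,0.0595322754667454
C114,6,0.0595322754667454
D102,1,1
R9,1,1
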