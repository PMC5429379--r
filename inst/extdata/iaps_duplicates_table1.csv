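desc,IAPS,valmn,valsd,valn,aromn,arosd,aron,dom1mn,dom1sd,dom1n,set
Spider,1230,4.09,,,4.85,,,4.58,,,1
Spider,1230,4.61,,,4.03,,,5.60,,,2
Horse,1590,7.18,,,4.74,,,5.54,,,2
Horse,1590,7.24,,,4.80,,,5.62,,,3
Rabbit,1610,7.82,,,3.08,,,6.77,,,1
Rabbit,1610,7.69,,,3.98,,,6.52,,,2
Coyote,1640,6.27,,,5.13,,,5.22,,,1
Coyote,1640,6.16,,,5.18,,,4.91,,,2
Cow,1670,6.81,,,3.05,,,6.53,,,1
Cow,1670,5.82,,,3.33,,,5.63,,,2
NeutFace,2210,4.38,,,3.56,,,5.03,,,1
NeutFace,2210,4.70,,,3.08,,,5.23,,,2
Mutilation,3000,1.45,,,7.26,,,2.99,,,1
Mutilation,3000,1.59,,,7.34,,,2.73,,,4
Mutilation,3010,1.71,,,7.16,,,2.88,,,2
Mutilation,3010,1.79,,,7.26,,,2.88,,,3
EroticFemale,4220,8.02,,,7.17,,,5.33,,,2
EroticFemale,4220,6.60,,,5.18,,,5.90,,,3
EroticMale,4520,7.04,,,5.48,,,5.48,,,2
EroticMale,4520,6.16,,,4.80,,,5.73,,,3
AimedGun,6200,2.71,,,6.21,,,3.35,,,1
AimedGun,6200,3.20,,,5.82,,,3.49,,,2
Exhaust,9090,3.56,,,3.97,,,4.51,,,2
Exhaust,9090,3.69,,,4.80,,,4.72,,,3
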