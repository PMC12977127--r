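# Example cerebellar color lookup table (id name R G B A).
# Synthetic convenience default following the standard lobular nomenclature
# (32 cortical regions: 11 hemispheric lobules per side + 10 vermal
# divisions, plus corpus medullare and the white-matter-tract patch that
# closes the surface at the peduncle cuts). Edit freely; this is not a
# released atlas table.
1    Left_I_III                      70  130 180   0
2    Left_IV                        205  62  78   0
3    Left_V                         245 245 245   0
4    Left_VI                        120  18 134   0
5    Left_Crus_I                    196  58 250   0
6    Left_Crus_II                     0 148   0   0
7    Left_VIIB                      220 248 164   0
8    Left_VIIIA                     230 148  34   0
9    Left_VIIIB                       0 118  14   0
10   Left_IX                        122 186 220   0
11   Left_X                         236  13 176   0
12   Right_I_III                     71 131 181   0
13   Right_IV                       206  63  79   0
14   Right_V                        244 244 244   0
15   Right_VI                       121  19 135   0
16   Right_Crus_I                   197  59 251   0
17   Right_Crus_II                    1 149   1   0
18   Right_VIIB                     221 249 165   0
19   Right_VIIIA                    231 149  35   0
20   Right_VIIIB                      1 119  15   0
21   Right_IX                       123 187 221   0
22   Right_X                        237  14 177   0
23   Vermis_I_II                     25 100  40   0
24   Vermis_III                     125 100  60   0
25   Vermis_IV_V                    100  25  80   0
26   Vermis_VI                       80 180 110   0
27   Vermis_VIIA                    255 165   0   0
28   Vermis_VIIB                    165  42  42   0
29   Vermis_VIIIA                    32 178 170   0
30   Vermis_VIIIB                   144 238 144   0
31   Vermis_IX                      255 215   0   0
32   Vermis_X                       255  99  71   0
33   Corpus_Medullare               250 255  50   0
34   White_Matter_Tracts            200 200 200   0
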