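# Synthetic codon usage table in Kazusa layout (generated, not a real organism)
UUU  3.5(    79)  UUC 21.7(   493)  UUA  8.3(   188)  UUG 36.2(   822)
UCU 11.7(   266)  UCC 16.0(   363)  UCA  4.1(    93)  UCG 25.9(   588)
UAU  5.4(   122)  UAC 22.6(   513)  UAA  0.4(    10)  UAG  0.2(     5)
UGU 12.6(   286)  UGC 26.5(   601)  UGA  0.7(    17)  UGG 24.5(   556)
CUU  1.7(    39)  CUC 22.5(   511)  CUA  4.7(   106)  CUG 10.3(   234)
CCU  5.9(   134)  CCC 20.2(   458)  CCA  1.9(    42)  CCG 33.2(   753)
CAU  5.1(   115)  CAC 35.7(   811)  CAA 12.6(   286)  CAG 19.9(   451)
CGU  9.0(   205)  CGC 28.4(   644)  CGA  6.7(   152)  CGG 14.6(   332)
AUU 13.1(   298)  AUC 30.5(   692)  AUA  4.3(    98)  AUG 30.6(   695)
ACU  5.2(   117)  ACC 22.2(   505)  ACA 12.5(   283)  ACG 23.1(   524)
AAU  7.8(   178)  AAC 15.7(   356)  AAA 10.4(   235)  AAG 22.9(   519)
AGU  9.3(   211)  AGC 37.3(   847)  AGA  1.0(    23)  AGG 17.2(   390)
GUU  8.4(   190)  GUC 22.7(   516)  GUA  8.0(   181)  GUG 39.3(   891)
GCU  5.2(   117)  GCC 35.8(   813)  GCA 13.0(   296)  GCG 34.8(   790)
GAU  7.5(   171)  GAC 34.2(   776)  GAA  1.1(    26)  GAG  8.9(   203)
GGU 10.4(   237)  GGC 20.4(   463)  GGA 11.0(   249)  GGG 23.6(   535)
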