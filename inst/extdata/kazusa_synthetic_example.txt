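UUU 32.5(   376)  UUC 19.1(   221)  UUA 11.1(   129)  UUG  6.7(    78)
UCU 12.5(   145)  UCC  6.8(    79)  UCA 11.5(   133)  UCG  7.5(    87)
UAU 34.0(   394)  UAC 18.7(   216)  UAA  0.0(     0)  UAG  0.0(     0)
UGU 34.5(   399)  UGC 20.0(   232)  UGA  0.0(     0)  UGG 11.1(   129)
CUU 11.4(   132)  CUC  6.4(    74)  CUA 12.4(   143)  CUG  6.0(    70)
CCU 17.0(   197)  CCC 10.3(   119)  CCA 17.4(   201)  CCG  8.4(    97)
CAU 35.5(   411)  CAC 18.9(   219)  CAA 35.1(   406)  CAG 17.1(   198)
CGU 12.5(   145)  CGC  7.9(    92)  CGA 13.3(   154)  CGG  6.6(    76)
AUU 16.4(   190)  AUC 19.8(   229)  AUA 17.7(   205)  AUG 13.7(   158)
ACU 18.7(   217)  ACC  9.4(   109)  ACA 15.4(   178)  ACG  9.4(   109)
AAU 35.6(   412)  AAC 21.1(   244)  AAA 34.8(   403)  AAG 20.0(   232)
AGU 11.0(   127)  AGC  5.8(    67)  AGA 10.5(   122)  AGG  5.4(    63)
GUU 18.8(   218)  GUC  9.3(   108)  GUA 17.8(   206)  GUG  9.5(   110)
GCU 18.1(   209)  GCC  9.8(   113)  GCA 16.5(   191)  GCG 10.9(   126)
GAU 33.4(   387)  GAC 18.5(   214)  GAA 35.2(   407)  GAG 19.4(   225)
GGU 19.6(   227)  GGC  9.8(   113)  GGA 17.4(   201)  GGG  8.8(   102)
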