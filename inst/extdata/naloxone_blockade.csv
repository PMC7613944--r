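dose,blockade,method,study
1,83,PET,Frost 1985
1,90,PET,Frost 1985
0.001,19,PET,Mayberg 1990
0.01,65,PET,Mayberg 1990
0.1,97,PET,Mayberg 1990
1.0,98,PET,Mayberg 1990
0.002,43,dual_detector,Kim 1997
0.03,81,dual_detector,Kim 1997
0,0,dual_detector,Villemagne 1994
0.0005,20,dual_detector,Villemagne 1994
0.001,40,dual_detector,Villemagne 1994
0.005,75,dual_detector,Villemagne 1994
0.01,100,dual_detector,Villemagne 1994
0.1,100,dual_detector,Villemagne 1994
0.5,100,dual_detector,Villemagne 1994
1.0,100,dual_detector,Villemagne 1994
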