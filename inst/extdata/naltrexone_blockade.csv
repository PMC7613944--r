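dose,blockade,method,study
2,27,PET,Rabiner 2011
5,43,PET,Rabiner 2011
5,46,PET,Rabiner 2011
5,58,PET,Rabiner 2011
15,61,PET,Rabiner 2011
50,92,PET,Rabiner 2011
50,98,PET,Rabiner 2011
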