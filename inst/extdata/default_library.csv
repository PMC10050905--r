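# hsqcmult-library v1
# CH resonances of the four reference metabolites; 1H/13C shifts in ppm
# (DSS-referenced, aqueous extract near pH 7) and one-bond 13C-13C scalar
# couplings in Hz, compiled from public references (HMDB, BMRB).
# Diastereotopic protons are separate records sharing delta_c and couplings.
metabolite,moiety,delta_h,delta_c,couplings
lactate,C2,4.10,69.33,C1:54.9;C3:37.1
lactate,C3,1.31,20.84,C2:37.1
alanine,C2,3.77,51.15,C1:53.8;C3:34.9
alanine,C3,1.46,16.99,C2:34.9
aspartate,C2,3.89,52.80,C1:53.9;C3:36.3
aspartate,C3a,2.68,37.42,C2:36.3;C4:50.9
aspartate,C3b,2.80,37.42,C2:36.3;C4:50.9
glutamate,C2,3.74,55.43,C1:53.4;C3:34.6
glutamate,C3a,2.04,27.73,C2:34.6;C4:33.8
glutamate,C3b,2.12,27.73,C2:34.6;C4:33.8
glutamate,C4,2.34,34.25,C3:33.8;C5:51.4
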