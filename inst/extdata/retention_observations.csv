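config,L_um,Y,group,particle,D_ef_m2_s,a
F118,55.5,2.30,HI,nanoAg,1.1982e-11,0.5020
F63,57.5,3.31,HI,nanoAg,0.9000e-11,0.3770
F1,49.3,6.18,HI,nanoAg,0.4924e-11,0.2063
F118+F63,113.0,5.62,HI,nanoAg,0.6433e-11,0.2695
F118+F63+F1,162.3,11.79,HI,nanoAg,0.4732e-11,0.1983
F1+F1,98.6,12.35,HI,nanoAg,0.3949e-11,0.1654
F1+F1+F1,147.9,18.53,HI,nanoAg,0.3625e-11,0.1519
F9*,47.9,5.43,HF,nanoAg,0.2308e-11,0.0967
F9*+F9*,95.9,10.87,HF,nanoAg,0.1911e-11,0.0801
F9*+F9*+F9*,143.8,16.30,HF,nanoAg,0.1773e-11,0.0743
F1+F9*+F1,146.5,17.79,mixed,nanoAg,0.1545e-11,0.0647
F9*+F1+F9*,145.2,17.04,mixed,nanoAg,0.1259e-11,0.0528
F118,55.5,2.30,HI,nanoCu,1.0818e-11,0.6043
F63,57.5,3.31,HI,nanoCu,0.9733e-11,0.5436
F1,49.3,6.18,HI,nanoCu,0.4587e-11,0.2562
F118+F63,113.0,5.62,HI,nanoCu,0.6947e-11,0.3881
F118+F63+F1,162.3,11.79,HI,nanoCu,0.3798e-11,0.2122
F1+F1,98.6,12.35,HI,nanoCu,0.1972e-11,0.1102
F1+F1+F1,147.9,18.53,HI,nanoCu,0.1359e-11,0.0759
F9*,47.9,5.43,HF,nanoCu,0.1414e-11,0.0790
F9*+F9*,95.9,10.87,HF,nanoCu,0.0881e-11,0.0492
F9*+F9*+F9*,143.8,16.30,HF,nanoCu,0.0877e-11,0.0490
F1+F9*+F1,146.5,17.79,mixed,nanoCu,0.0445e-11,0.0249
F9*+F1+F9*,145.2,17.04,mixed,nanoCu,0.0220e-11,0.0123
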