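ID,TIME,DV,MDV,ASSAY,GA,BWT,AKI,DEATH
1,1.0,0.95,0,idms,39,3400,0,0
1,2.5,0.71,0,idms,39,3400,0,0
1,6.0,0.48,0,idms,39,3400,0,0
2,0.8,1.21,0,jaffe,36,2600,1,0
2,3.2,1.34,0,jaffe,36,2600,1,0
3,1.5,0.88,0,idms,41,3900,0,1
3,4.0,0.61,0,idms,41,3900,0,1
3,9.5,0.42,0,idms,41,3900,0,1
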