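genotype,n,measure,mean_mm3,sd_mm3
WT,26,GM,316.51,9.63
WT,26,WM,123.89,9.52
WT,26,BV,440.40,15.48
WT,26,vCSF,2.39,0.98
WT,26,eCSF,26.70,15.60
WT,26,TIV,469.49,15.34
Tc1,29,GM,363.33,21.03
Tc1,29,WM,139.57,11.29
Tc1,29,BV,502.91,28.67
Tc1,29,vCSF,3.43,1.25
Tc1,29,eCSF,29.84,19.18
Tc1,29,TIV,536.19,28.33
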