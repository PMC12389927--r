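scale,group,n,mean_change,sd_change
MORE,experimental,8,2.25,4.10
MORE,control,8,-1.12,4.94
FIM,experimental,8,3.00,4.66
FIM,control,8,1.50,4.24
FMA-UE,experimental,8,9.38,9.90
FMA-UE,control,8,5.38,22.88
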