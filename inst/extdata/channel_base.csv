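kind,reversal_mV,base_value,units,multipliers_tested,multiplier_chosen
lk,-52,0.25,mS/cm2,0.5;1.0;1.5,1.0
na,50,10.0,mS/cm2,0.0;0.5;1.0;1.5;2.0;3.0,3.0
kf,-81.5,2.5,mS/cm2,0.5;1.0;1.5,1.0
ks,-81.5,2.0,mS/cm2,0.5;1.0;1.5,1.0
ca,NA,0.016,cm/s,0.0;0.5;1.0;1.5,1.0
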