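channel,gate,rate,branch,A,B,C,D,E
ca,m_ca,alpha,all,4.05,0,1.0,-15.32,-13.57
ca,m_ca,beta,low,1.24,0.093,-1.0,10.63,1.0
ca,m_ca,beta,high,1.28,0,1.0,5.39,12.11
kf,n_kf,alpha,all,5.06,0.0666,5.12,-18.396,-25.42
kf,n_kf,beta,all,0.505,0,0.0,28.7,34.6
ks,n_ks,alpha,all,0.462,0.008204,4.59,-4.21,-11.97
ks,n_ks,beta,all,0.0924,-0.001353,1.615,210000,333000
na,m_na,alpha,all,8.67,0,1.0,-1.01,-12.56
na,m_na,beta,all,3.82,0,1.0,9.01,9.69
na,h_na,alpha,all,0.08,0,0.0,38.88,26.0
na,h_na,beta,all,4.08,0,1.0,-5.09,-10.21
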