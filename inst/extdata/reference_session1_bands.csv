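condition,band,mean,sd,t,d
CS1,delta,-0.10,1.06,-0.370,0.097
CS1,theta,0.12,0.19,2.432,0.625
CS1,alpha,0.07,0.41,0.714,0.179
CS1,beta,0.03,0.07,1.518,0.393
CS1,gamma,0.01,0.05,0.896,0.235
CS2,delta,0.08,0.66,0.472,0.119
CS2,theta,0.18,0.20,3.461,0.890
CS2,alpha,0.22,0.82,1.025,0.264
CS2,beta,0.06,0.23,1.024,0.265
CS2,gamma,0.01,0.19,0.192,0.048
CS3,delta,-0.08,0.96,-0.332,0.088
CS3,theta,0.13,0.15,3.266,0.843
CS3,alpha,-0.01,0.46,-0.079,0.023
CS3,beta,0.03,0.12,0.8555,0.230
CS3,gamma,0.02,0.10,0.972,0.249
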