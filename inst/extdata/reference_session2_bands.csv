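condition,band,mean,sd,t,d
SHAM,delta,-0.05,1.62,-0.131,0.033
SHAM,theta,0.07,0.97,0.286,0.074
SHAM,alpha,-0.59,1.06,-2.143,0.553
SHAM,beta,-0.05,0.20,-1.005,0.260
SHAM,gamma,0.00,0.29,-0.092,0.026
BB,delta,0.25,0.80,1.888,0.307
BB,theta,0.40,0.59,2.603,0.672
BB,alpha,-0.96,0.86,-4.340,1.116
BB,beta,-0.02,0.32,-0.246,0.065
BB,gamma,0.13,0.29,1.672,0.416
AT,delta,0.01,2.01,0.017,0.005
AT,theta,0.28,0.51,2.093,0.538
AT,alpha,-1.32,0.96,-5.347,1.381
AT,beta,0.04,0.20,0.756,0.192
AT,gamma,0.08,0.23,1.308,0.326
CS,delta,0.32,1.30,0.943,0.244
CS,theta,0.48,0.74,2.516,0.650
CS,alpha,-1.39,1.19,-4.539,1.176
CS,beta,-0.09,0.10,-3.432,0.884
CS,gamma,-0.02,0.21,-0.318,0.076
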