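condition,factor,mean,sd,t,d
CS1,anger,-1.93,1.91,-3.925,1.013
CS1,tension,-2.67,3.18,-3.250,0.839
CS1,depression,-1.60,1.55,-4.000,1.032
CS1,vigor,-2.13,3.27,-2.526,0.652
CS1,fatigue,-1.80,3.90,-1.789,0.462
CS1,confusion,-2.20,1.86,-4.582,1.183
CS1,happy,-0.27,2.71,-0.380,0.098
CS1,calmness,-1.00,1.65,-2.350,0.606
CS2,anger,-2.87,2.53,-4.385,1.132
CS2,tension,-3.00,2.42,-4.800,1.239
CS2,depression,-1.87,1.51,-4.802,1.239
CS2,vigor,-2.27,2.66,-3.302,0.852
CS2,fatigue,-1.53,3.87,-1.534,0.396
CS2,confusion,-2.33,1.76,-5.136,1.326
CS2,happy,1.33,2.09,2.467,0.636
CS2,calmness,0.33,1.72,0.751,0.193
CS3,anger,-2.73,2.66,-3.982,1.028
CS3,tension,-3.00,2.54,-4.582,1.183
CS3,depression,-2.07,2.09,-3.836,0.990
CS3,vigor,-1.87,3.31,-2.181,0.563
CS3,fatigue,-1.33,3.81,-1.355,0.349
CS3,confusion,-1.67,2.41,-2.678,0.691
CS3,happy,0.73,2.60,1.090,0.281
CS3,calmness,0.93,1.75,2.064,0.532
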