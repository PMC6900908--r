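condition,factor,mean,sd,t,d
SHAM,anger,0.73,1.49,1.910,0.493
SHAM,tension,0.53,1.41,1.467,0.378
SHAM,depression,-0.47,1.30,-1.388,0.358
SHAM,vigor,-3.33,3.48,-3.712,0.958
SHAM,fatigue,2.73,2.55,4.153,1.072
SHAM,confusion,0.53,1.60,1.292,0.333
SHAM,happy,-2.53,2.61,-3.450,0.890
SHAM,calmness,-0.73,2.25,-1.261,0.325
BB,anger,1.40,2.06,2.627,0.678
BB,tension,-1.53,3.60,-1.648,0.425
BB,depression,-0.80,2.91,-1.065,0.275
BB,vigor,-4.20,3.41,-4.776,1.233
BB,fatigue,1.47,2.77,2.047,0.528
BB,confusion,-1.13,2.45,-1.794,0.463
BB,happy,-1.87,3.38,-2.140,0.552
BB,calmness,-1.40,2.44,-2.218,0.572
AT,anger,-1.07,2.69,-1.538,0.397
AT,tension,-1.93,2.94,-2.547,0.657
AT,depression,-1.33,2.66,-1.938,0.500
AT,vigor,-4.27,3.06,-5.403,1.395
AT,fatigue,1.67,3.27,1.976,0.510
AT,confusion,-1.13,1.92,-2.283,0.589
AT,happy,-0.20,2.68,-0.289,0.074
AT,calmness,1.07,1.75,2.359,0.609
CS,anger,-1.87,1.64,-4.403,1.137
CS,tension,-2.00,1.96,-3.944,1.018
CS,depression,-0.80,1.82,-1.701,0.439
CS,vigor,-1.80,3.17,-2.201,0.568
CS,fatigue,1.67,2.85,2.268,0.585
CS,confusion,-1.00,2.24,-1.732,0.447
CS,happy,0.07,2.28,0.113,0.029
CS,calmness,1.87,2.75,2.630,0.679
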