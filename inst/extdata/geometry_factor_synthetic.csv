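half_crack_angle_deg,rm_over_t,factor
0,1.5,0.612
0,2,0.6336
0,3,0.6768
0,4,0.72
0,5,0.7632
0,6,0.8064
0,8,0.8928
0,10,0.9792
10,1.5,0.623863
10,2,0.645882
10,3,0.68992
10,4,0.733957
10,5,0.777994
10,6,0.822032
10,8,0.910107
10,10,0.998181
20,1.5,0.650544
20,2,0.673505
20,3,0.719425
20,4,0.765346
20,5,0.811267
20,6,0.857188
20,8,0.949029
20,10,1.040871
30,1.5,0.688792
30,2,0.713102
30,3,0.761723
30,4,0.810343
30,5,0.858964
30,6,0.907585
30,8,1.004826
30,10,1.102067
40,1.5,0.737231
40,2,0.763251
40,3,0.815291
40,4,0.86733
40,5,0.91937
40,6,0.97141
40,8,1.07549
40,10,1.179569
50,1.5,0.795003
50,2,0.823062
50,3,0.87918
50,4,0.935298
50,5,0.991416
50,6,1.047533
50,8,1.159769
50,10,1.272005
60,1.5,0.861498
60,2,0.891903
60,3,0.952715
60,4,1.013527
60,5,1.074338
60,6,1.13515
60,8,1.256773
60,10,1.378396
70,1.5,0.936247
70,2,0.969291
70,3,1.035379
70,4,1.101467
70,5,1.167555
70,6,1.233643
70,8,1.365819
70,10,1.497995
80,1.5,1.018876
80,2,1.054836
80,3,1.126757
80,4,1.198678
80,5,1.270599
80,6,1.342519
80,8,1.486361
80,10,1.630202
90,1.5,1.109075
90,2,1.148218
90,3,1.226506
90,4,1.304794
90,5,1.383081
90,6,1.461369
90,8,1.617944
90,10,1.774519
100,1.5,1.206579
100,2,1.249164
100,3,1.334334
100,4,1.419504
100,5,1.504674
100,6,1.589845
100,8,1.760185
100,10,1.930526
110,1.5,1.31116
110,2,1.357437
110,3,1.449989
110,4,1.542542
110,5,1.635094
110,6,1.727647
110,8,1.912752
110,10,2.097857
120,1.5,1.42262
120,2,1.47283
120,3,1.573251
120,4,1.673671
120,5,1.774091
120,6,1.874511
120,8,2.075352
120,10,2.276192
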