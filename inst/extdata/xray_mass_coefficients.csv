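# X-ray mass attenuation (mu_rho) and mass energy-absorption (mu_en_rho)
# coefficients, cm^2/g, on the standard compilation energy grid 1-500 keV.
# Values transcribed from the standard published compilations of photon
# cross sections and mass energy-absorption coefficients (NIST XCOM /
# Hubbell & Seltzer style tables). Absorption edges are represented by
# duplicated energy nodes (below-edge row first, above-edge row second).
# For the minor soil constituents Ar, K, Ca and Ti the energy-absorption
# column is left empty and is reconstructed at load time from the
# attenuation residual (photoelectric) plus the Klein-Nishina
# energy-transfer component; these elements also carry a larger
# transcription uncertainty (several percent) than H/C/N/O/Al/Si/Fe.
# Columns: element symbol, atomic number Z, atomic mass A (g/mol),
# photon energy (keV), mu/rho (cm^2/g), mu_en/rho (cm^2/g or empty).
element,Z,A,energy_kev,mu_rho,mu_en_rho
H,1,1.008,1,7.217,6.820
H,1,1.008,1.5,2.148,1.752
H,1,1.008,2,1.059,0.6643
H,1,1.008,3,0.5612,0.1700
H,1,1.008,4,0.4546,0.0730
H,1,1.008,5,0.4193,0.0386
H,1,1.008,6,0.4042,0.0230
H,1,1.008,8,0.3914,0.00975
H,1,1.008,10,0.3854,0.00986
H,1,1.008,15,0.3764,0.01102
H,1,1.008,20,0.3695,0.01331
H,1,1.008,30,0.3570,0.01868
H,1,1.008,40,0.3458,0.02315
H,1,1.008,50,0.3355,0.02709
H,1,1.008,60,0.3260,0.03053
H,1,1.008,80,0.3091,0.03620
H,1,1.008,100,0.2944,0.04063
H,1,1.008,150,0.2651,0.04813
H,1,1.008,200,0.2429,0.05254
H,1,1.008,300,0.2112,0.05695
H,1,1.008,400,0.1893,0.05860
H,1,1.008,500,0.1729,0.05898
C,6,12.011,1,2211,2209
C,6,12.011,1.5,700.2,699.0
C,6,12.011,2,303.0,302.0
C,6,12.011,3,91.00,90.30
C,6,12.011,4,37.78,37.30
C,6,12.011,5,19.12,18.84
C,6,12.011,6,10.95,10.74
C,6,12.011,8,4.576,4.360
C,6,12.011,10,2.373,2.078
C,6,12.011,15,0.8071,0.5627
C,6,12.011,20,0.4420,0.2238
C,6,12.011,30,0.2562,0.06614
C,6,12.011,40,0.2076,0.03343
C,6,12.011,50,0.1871,0.02397
C,6,12.011,60,0.1753,0.02098
C,6,12.011,80,0.1610,0.02037
C,6,12.011,100,0.1514,0.02147
C,6,12.011,150,0.1347,0.02449
C,6,12.011,200,0.1229,0.02655
C,6,12.011,300,0.1066,0.02870
C,6,12.011,400,0.09546,0.02950
C,6,12.011,500,0.08715,0.02969
N,7,14.007,1,3311,3306
N,7,14.007,1.5,1083,1080
N,7,14.007,2,476.9,475.4
N,7,14.007,3,146.0,145.0
N,7,14.007,4,63.00,62.40
N,7,14.007,5,33.00,32.50
N,7,14.007,6,19.40,19.00
N,7,14.007,8,8.090,7.750
N,7,14.007,10,3.879,3.545
N,7,14.007,15,1.236,1.000
N,7,14.007,20,0.6178,0.4100
N,7,14.007,30,0.3066,0.1200
N,7,14.007,40,0.2288,0.05800
N,7,14.007,50,0.1980,0.03700
N,7,14.007,60,0.1817,0.02880
N,7,14.007,80,0.1639,0.02390
N,7,14.007,100,0.1529,0.02380
N,7,14.007,150,0.1353,0.02500
N,7,14.007,200,0.1233,0.02640
N,7,14.007,300,0.1068,0.02850
N,7,14.007,400,0.09557,0.02930
N,7,14.007,500,0.08719,0.02950
O,8,15.999,1,4590,4576
O,8,15.999,1.5,1549,1545
O,8,15.999,2,694.4,692.0
O,8,15.999,3,217.1,215.6
O,8,15.999,4,94.50,93.70
O,8,15.999,5,47.90,47.20
O,8,15.999,6,27.70,27.20
O,8,15.999,8,11.90,11.35
O,8,15.999,10,5.952,5.565
O,8,15.999,15,1.836,1.545
O,8,15.999,20,0.8651,0.6179
O,8,15.999,30,0.3779,0.1729
O,8,15.999,40,0.2585,0.07529
O,8,15.999,50,0.2132,0.04414
O,8,15.999,60,0.1907,0.03207
O,8,15.999,80,0.1678,0.02468
O,8,15.999,100,0.1551,0.02355
O,8,15.999,150,0.1361,0.02506
O,8,15.999,200,0.1237,0.02679
O,8,15.999,300,0.1070,0.02877
O,8,15.999,400,0.09566,0.02954
O,8,15.999,500,0.08729,0.02977
Al,13,26.982,1,1185,1183
Al,13,26.982,1.5,402.2,400.2
Al,13,26.982,2,2263,2250
Al,13,26.982,3,788.0,784.0
Al,13,26.982,4,360.5,358.1
Al,13,26.982,5,193.4,191.9
Al,13,26.982,6,115.3,114.2
Al,13,26.982,8,50.33,49.59
Al,13,26.982,10,26.23,25.43
Al,13,26.982,15,7.955,7.487
Al,13,26.982,20,3.441,3.094
Al,13,26.982,30,1.128,0.8778
Al,13,26.982,40,0.5685,0.3601
Al,13,26.982,50,0.3681,0.1840
Al,13,26.982,60,0.2778,0.1099
Al,13,26.982,80,0.2018,0.05511
Al,13,26.982,100,0.1704,0.03794
Al,13,26.982,150,0.1378,0.02827
Al,13,26.982,200,0.1223,0.02745
Al,13,26.982,300,0.1042,0.02816
Al,13,26.982,400,0.09276,0.02862
Al,13,26.982,500,0.08445,0.02868
Si,14,28.085,1,1570,1567
Si,14,28.085,1.5,535.5,533.0
Si,14,28.085,2,2777,2770
Si,14,28.085,3,978.4,974.0
Si,14,28.085,4,452.9,450.0
Si,14,28.085,5,245.0,243.0
Si,14,28.085,6,147.0,145.7
Si,14,28.085,8,64.68,63.60
Si,14,28.085,10,33.89,32.90
Si,14,28.085,15,10.34,9.794
Si,14,28.085,20,4.464,4.076
Si,14,28.085,30,1.436,1.164
Si,14,28.085,40,0.7012,0.4782
Si,14,28.085,50,0.4385,0.2430
Si,14,28.085,60,0.3207,0.1434
Si,14,28.085,80,0.2228,0.06896
Si,14,28.085,100,0.1835,0.04513
Si,14,28.085,150,0.1448,0.03086
Si,14,28.085,200,0.1275,0.02905
Si,14,28.085,300,0.1082,0.02932
Si,14,28.085,400,0.09614,0.02968
Si,14,28.085,500,0.08748,0.02971
Ar,18,39.948,1,5210,
Ar,18,39.948,1.5,1543,
Ar,18,39.948,2,651.0,
Ar,18,39.948,3,193.0,
Ar,18,39.948,3.2029,159.0,
Ar,18,39.948,3.2029,1430,
Ar,18,39.948,4,820.0,
Ar,18,39.948,5,440.0,
Ar,18,39.948,6,262.0,
Ar,18,39.948,8,116.0,
Ar,18,39.948,10,58.00,
Ar,18,39.948,15,17.60,
Ar,18,39.948,20,7.600,
Ar,18,39.948,30,2.360,
Ar,18,39.948,40,1.070,
Ar,18,39.948,50,0.6300,
Ar,18,39.948,60,0.4300,
Ar,18,39.948,80,0.2650,
Ar,18,39.948,100,0.2020,
Ar,18,39.948,150,0.1430,
Ar,18,39.948,200,0.1180,
Ar,18,39.948,300,0.09560,
Ar,18,39.948,400,0.08690,
Ar,18,39.948,500,0.07930,
K,19,39.098,1,8400,
K,19,39.098,1.5,2489,
K,19,39.098,2,1050,
K,19,39.098,3,311.0,
K,19,39.098,3.6074,180.0,
K,19,39.098,3.6074,1580,
K,19,39.098,4,1177,
K,19,39.098,5,602.0,
K,19,39.098,6,349.0,
K,19,39.098,8,147.0,
K,19,39.098,10,75.50,
K,19,39.098,15,23.00,
K,19,39.098,20,9.750,
K,19,39.098,30,3.030,
K,19,39.098,40,1.400,
K,19,39.098,50,0.8100,
K,19,39.098,60,0.5430,
K,19,39.098,80,0.3210,
K,19,39.098,100,0.2360,
K,19,39.098,150,0.1600,
K,19,39.098,200,0.1330,
K,19,39.098,300,0.1070,
K,19,39.098,400,0.09470,
K,19,39.098,500,0.08560,
Ca,20,40.078,1,10670,
Ca,20,40.078,1.5,3160,
Ca,20,40.078,2,1333,
Ca,20,40.078,3,396.0,
Ca,20,40.078,4.0381,163.0,
Ca,20,40.078,4.0381,1410,
Ca,20,40.078,5,745.0,
Ca,20,40.078,6,432.0,
Ca,20,40.078,8,184.0,
Ca,20,40.078,10,93.40,
Ca,20,40.078,15,28.30,
Ca,20,40.078,20,12.20,
Ca,20,40.078,30,4.000,
Ca,20,40.078,40,1.690,
Ca,20,40.078,50,0.9500,
Ca,20,40.078,60,0.6300,
Ca,20,40.078,80,0.3700,
Ca,20,40.078,100,0.2650,
Ca,20,40.078,150,0.1770,
Ca,20,40.078,200,0.1470,
Ca,20,40.078,300,0.1200,
Ca,20,40.078,400,0.09850,
Ca,20,40.078,500,0.08930,
Ti,22,47.867,1,5869,
Ti,22,47.867,1.5,2210,
Ti,22,47.867,2,986.0,
Ti,22,47.867,3,332.3,
Ti,22,47.867,4,151.7,
Ti,22,47.867,4.9664,83.80,
Ti,22,47.867,4.9664,687.8,
Ti,22,47.867,6,432.0,
Ti,22,47.867,8,202.3,
Ti,22,47.867,10,110.7,
Ti,22,47.867,15,35.90,
Ti,22,47.867,20,15.90,
Ti,22,47.867,30,4.972,
Ti,22,47.867,40,2.214,
Ti,22,47.867,50,1.213,
Ti,22,47.867,60,0.7661,
Ti,22,47.867,80,0.4052,
Ti,22,47.867,100,0.2720,
Ti,22,47.867,150,0.1640,
Ti,22,47.867,200,0.1300,
Ti,22,47.867,300,0.1020,
Ti,22,47.867,400,0.08900,
Ti,22,47.867,500,0.08100,
Fe,26,55.845,1,9085,9052
Fe,26,55.845,1.5,3399,3388
Fe,26,55.845,2,1626,1620
Fe,26,55.845,3,557.6,555.0
Fe,26,55.845,4,256.7,254.5
Fe,26,55.845,5,139.8,138.3
Fe,26,55.845,6,84.84,83.70
Fe,26,55.845,7.112,53.19,52.30
Fe,26,55.845,7.112,407.6,297.0
Fe,26,55.845,8,305.6,226.0
Fe,26,55.845,10,170.6,136.9
Fe,26,55.845,15,57.08,48.96
Fe,26,55.845,20,25.68,22.50
Fe,26,55.845,30,8.176,7.251
Fe,26,55.845,40,3.629,3.155
Fe,26,55.845,50,1.958,1.638
Fe,26,55.845,60,1.205,0.9555
Fe,26,55.845,80,0.5952,0.4104
Fe,26,55.845,100,0.3717,0.2177
Fe,26,55.845,150,0.1964,0.07961
Fe,26,55.845,200,0.1460,0.04825
Fe,26,55.845,300,0.1099,0.03361
Fe,26,55.845,400,0.09400,0.03039
Fe,26,55.845,500,0.08414,0.02914
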