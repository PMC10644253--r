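label,x,y
Fc5,-0.5954,0.1438
Fc3,-0.3868,0.1460
Fc1,-0.1882,0.1437
Fcz,0.0020,0.1443
Fc2,0.1941,0.1475
Fc4,0.3939,0.1500
Fc6,0.5984,0.1500
C5,-0.5823,-0.0998
C3,-0.3797,-0.0676
C1,-0.1837,-0.0507
Cz,0.0019,-0.0439
C2,0.1933,-0.0494
C4,0.3892,-0.0632
C6,0.5891,-0.0902
Cp5,-0.5183,-0.3031
Cp3,-0.3399,-0.2514
Cp1,-0.1662,-0.2213
Cpz,0.0017,-0.2139
Cp2,0.1796,-0.2202
Cp4,0.3519,-0.2464
Cp6,0.5284,-0.2923
Fp1,-0.2629,0.7494
Fpz,0.0010,0.7657
Fp2,0.2636,0.7491
Af7,-0.5085,0.6358
Af3,-0.2559,0.5834
Afz,0.0016,0.5574
Af4,0.2653,0.5773
Af8,0.5087,0.6356
F7,-0.7042,0.4257
F5,-0.5264,0.3922
F3,-0.3466,0.3664
F1,-0.1694,0.3506
Fz,0.0019,0.3476
F2,0.1816,0.3544
F4,0.3567,0.3737
F6,0.5353,0.3928
F8,0.7036,0.4279
Ft7,-0.8091,0.1414
Ft8,0.8073,0.1521
T7,-0.7944,-0.1512
T8,0.7967,-0.1407
T9,-0.9830,-0.1811
T10,0.9822,-0.1878
Tp7,-0.6957,-0.3774
Tp8,0.6988,-0.3721
P7,-0.5392,-0.5468
P5,-0.4136,-0.4690
P3,-0.2791,-0.4149
P1,-0.1367,-0.3846
Pz,0.0015,-0.3738
P2,0.1501,-0.3786
P4,0.2894,-0.4085
P6,0.4178,-0.4672
P8,0.5431,-0.5432
Po7,-0.3648,-0.6488
Po3,-0.2028,-0.5602
Poz,0.0011,-0.5349
Po4,0.2052,-0.5627
Po8,0.3689,-0.6469
O1,-0.1822,-0.6964
Oz,0.0007,-0.6953
O2,0.1851,-0.6957
Iz,0.0000,-0.8489
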