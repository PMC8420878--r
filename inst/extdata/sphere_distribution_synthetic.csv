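"radius_um","volume_fraction"
1,0.179444
1.75,0.274681
2.5,0.187416
3.25,0.102238
4,0.0520651
4.75,0.0261427
5.5,0.01323
6.25,0.0068103
7,0.00357896
7.75,0.00192219
8.5,0.00105491
9.25,0.000591136
10,0.000337889
10.75,0.000196787
11.5,0.000116647
12.25,7.02968e-05
13,4.30272e-05
13.75,2.6723e-05
14.5,1.68259e-05
15.25,1.07317e-05
16,6.92842e-06
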