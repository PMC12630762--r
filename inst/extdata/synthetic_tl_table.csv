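"range_m","source_depth_m","tl_db"
100,600,42.35
200,600,49.321
300,600,53.792
400,600,57.241
500,600,60.129
600,600,62.663
700,600,64.952
800,600,67.062
900,600,69.035
1000,600,70.9
1100,600,72.678
1200,600,74.384
1300,600,76.029
1400,600,77.623
1500,600,79.172
1600,600,80.682
1700,600,82.159
1800,600,83.605
1900,600,85.025
2000,600,86.421
2100,600,87.794
2200,600,89.148
2300,600,90.485
2400,600,91.804
2500,600,93.109
2600,600,94.399
2700,600,95.677
2800,600,96.943
2900,600,98.198
3000,600,99.442
3100,600,100.677
3200,600,101.903
3300,600,103.12
3400,600,104.33
3500,600,105.531
3600,600,106.726
3700,600,107.914
3800,600,109.096
3900,600,110.271
4000,600,111.441
4100,600,112.606
4200,600,113.765
4300,600,114.919
4400,600,116.069
4500,600,117.214
4600,600,118.355
4700,600,119.492
4800,600,120.625
4900,600,121.754
5000,600,122.879
5100,600,124.001
5200,600,125.12
5300,600,126.236
5400,600,127.348
5500,600,128.457
5600,600,129.564
5700,600,130.667
5800,600,131.769
5900,600,132.867
6000,600,133.963
100,900,41.75
200,900,48.721
300,900,53.192
400,900,56.641
500,900,59.529
600,900,62.063
700,900,64.352
800,900,66.462
900,900,68.435
1000,900,70.3
1100,900,72.078
1200,900,73.784
1300,900,75.429
1400,900,77.023
1500,900,78.572
1600,900,80.082
1700,900,81.559
1800,900,83.005
1900,900,84.425
2000,900,85.821
2100,900,87.194
2200,900,88.548
2300,900,89.885
2400,900,91.204
2500,900,92.509
2600,900,93.799
2700,900,95.077
2800,900,96.343
2900,900,97.598
3000,900,98.842
3100,900,100.077
3200,900,101.303
3300,900,102.52
3400,900,103.73
3500,900,104.931
3600,900,106.126
3700,900,107.314
3800,900,108.496
3900,900,109.671
4000,900,110.841
4100,900,112.006
4200,900,113.165
4300,900,114.319
4400,900,115.469
4500,900,116.614
4600,900,117.755
4700,900,118.892
4800,900,120.025
4900,900,121.154
5000,900,122.279
5100,900,123.401
5200,900,124.52
5300,900,125.636
5400,900,126.748
5500,900,127.857
5600,900,128.964
5700,900,130.067
5800,900,131.169
5900,900,132.267
6000,900,133.363
100,1200,41.15
200,1200,48.121
300,1200,52.592
400,1200,56.041
500,1200,58.929
600,1200,61.463
700,1200,63.752
800,1200,65.862
900,1200,67.835
1000,1200,69.7
1100,1200,71.478
1200,1200,73.184
1300,1200,74.829
1400,1200,76.423
1500,1200,77.972
1600,1200,79.482
1700,1200,80.959
1800,1200,82.405
1900,1200,83.825
2000,1200,85.221
2100,1200,86.594
2200,1200,87.948
2300,1200,89.285
2400,1200,90.604
2500,1200,91.909
2600,1200,93.199
2700,1200,94.477
2800,1200,95.743
2900,1200,96.998
3000,1200,98.242
3100,1200,99.477
3200,1200,100.703
3300,1200,101.92
3400,1200,103.13
3500,1200,104.331
3600,1200,105.526
3700,1200,106.714
3800,1200,107.896
3900,1200,109.071
4000,1200,110.241
4100,1200,111.406
4200,1200,112.565
4300,1200,113.719
4400,1200,114.869
4500,1200,116.014
4600,1200,117.155
4700,1200,118.292
4800,1200,119.425
4900,1200,120.554
5000,1200,121.679
5100,1200,122.801
5200,1200,123.92
5300,1200,125.036
5400,1200,126.148
5500,1200,127.257
5600,1200,128.364
5700,1200,129.467
5800,1200,130.569
5900,1200,131.667
6000,1200,132.763
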