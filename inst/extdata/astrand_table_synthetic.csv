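# Synthetic reconstruction of the Astrand-Ryhming cycle-ergometer nomogram.
# NOT a transcription of the original published tables: values are generated
# from the nomogram underlying linear HR-%VO2max model with sex-specific
# anchors (men: HRmax 195, HR intercept 61 bpm; women: HRmax 198, 72 bpm)
# and a cycling oxygen cost of 2 mL O2 per kpm plus 0.3 L/min baseline
# (1 W = 6.116 kpm/min). Uncorrected VO2max in L/min on a (work rate, HR)
# grid; multiply by the age-correction factor (astrand_age_correction.csv).
sex,work_rate_w,hr_bpm,vo2max_l_min
female,25,120,1.590
female,25,125,1.440
female,25,130,1.316
female,25,135,1.212
female,25,140,1.123
female,25,145,1.046
female,25,150,0.979
female,25,155,0.920
female,25,160,0.867
female,25,165,0.821
female,25,170,0.779
female,50,120,2.393
female,50,125,2.167
female,50,130,1.980
female,50,135,1.823
female,50,140,1.689
female,50,145,1.573
female,50,150,1.473
female,50,155,1.384
female,50,160,1.305
female,50,165,1.235
female,50,170,1.172
female,75,120,3.196
female,75,125,2.894
female,75,130,2.645
female,75,135,2.435
female,75,140,2.256
female,75,145,2.101
female,75,150,1.967
female,75,155,1.848
female,75,160,1.743
female,75,165,1.649
female,75,170,1.565
female,100,120,3.998
female,100,125,3.621
female,100,130,3.309
female,100,135,3.046
female,100,140,2.822
female,100,145,2.629
female,100,150,2.461
female,100,155,2.312
female,100,160,2.181
female,100,165,2.064
female,100,170,1.958
female,125,120,4.801
female,125,125,4.348
female,125,130,3.973
female,125,135,3.658
female,125,140,3.389
female,125,145,3.157
female,125,150,2.955
female,125,155,2.777
female,125,160,2.619
female,125,165,2.478
female,125,170,2.352
female,150,120,5.604
female,150,125,5.075
female,150,130,4.638
female,150,135,4.270
female,150,140,3.956
female,150,145,3.685
female,150,150,3.449
female,150,155,3.241
female,150,160,3.057
female,150,165,2.892
female,150,170,2.745
female,175,120,6.407
female,175,125,5.802
female,175,130,5.302
female,175,135,4.881
female,175,140,4.522
female,175,145,4.213
female,175,150,3.943
female,175,155,3.705
female,175,160,3.494
female,175,165,3.307
female,175,170,3.138
female,200,120,7.209
female,200,125,6.529
female,200,130,5.966
female,200,135,5.493
female,200,140,5.089
female,200,145,4.740
female,200,150,4.436
female,200,155,4.169
female,200,160,3.932
female,200,165,3.721
female,200,170,3.531
female,225,120,8.012
female,225,125,7.256
female,225,130,6.631
female,225,135,6.104
female,225,140,5.656
female,225,145,5.268
female,225,150,4.930
female,225,155,4.633
female,225,160,4.370
female,225,165,4.135
female,225,170,3.924
female,250,120,8.815
female,250,125,7.983
female,250,130,7.295
female,250,135,6.716
female,250,140,6.222
female,250,145,5.796
female,250,150,5.424
female,250,155,5.098
female,250,160,4.808
female,250,165,4.550
female,250,170,4.317
male,25,120,1.376
male,25,125,1.268
male,25,130,1.176
male,25,135,1.097
male,25,140,1.028
male,25,145,0.966
male,25,150,0.912
male,25,155,0.864
male,25,160,0.820
male,25,165,0.781
male,25,170,0.745
male,50,120,2.070
male,50,125,1.909
male,50,130,1.770
male,50,135,1.651
male,50,140,1.546
male,50,145,1.454
male,50,150,1.373
male,50,155,1.300
male,50,160,1.234
male,50,165,1.175
male,50,170,1.121
male,75,120,2.765
male,75,125,2.549
male,75,130,2.364
male,75,135,2.204
male,75,140,2.065
male,75,145,1.942
male,75,150,1.833
male,75,155,1.735
male,75,160,1.648
male,75,165,1.569
male,75,170,1.497
male,100,120,3.459
male,100,125,3.189
male,100,130,2.958
male,100,135,2.758
male,100,140,2.584
male,100,145,2.430
male,100,150,2.293
male,100,155,2.171
male,100,160,2.062
male,100,165,1.963
male,100,170,1.873
male,125,120,4.154
male,125,125,3.829
male,125,130,3.552
male,125,135,3.312
male,125,140,3.102
male,125,145,2.918
male,125,150,2.754
male,125,155,2.607
male,125,160,2.476
male,125,165,2.357
male,125,170,2.248
male,150,120,4.849
male,150,125,4.470
male,150,130,4.146
male,150,135,3.866
male,150,140,3.621
male,150,145,3.406
male,150,150,3.214
male,150,155,3.043
male,150,160,2.890
male,150,165,2.751
male,150,170,2.624
male,175,120,5.543
male,175,125,5.110
male,175,130,4.740
male,175,135,4.419
male,175,140,4.140
male,175,145,3.893
male,175,150,3.675
male,175,155,3.479
male,175,160,3.303
male,175,165,3.145
male,175,170,3.000
male,200,120,6.238
male,200,125,5.750
male,200,130,5.334
male,200,135,4.973
male,200,140,4.658
male,200,145,4.381
male,200,150,4.135
male,200,155,3.915
male,200,160,3.717
male,200,165,3.539
male,200,170,3.376
male,225,120,6.932
male,225,125,6.391
male,225,130,5.927
male,225,135,5.527
male,225,140,5.177
male,225,145,4.869
male,225,150,4.595
male,225,155,4.351
male,225,160,4.131
male,225,165,3.933
male,225,170,3.752
male,250,120,7.627
male,250,125,7.031
male,250,130,6.521
male,250,135,6.081
male,250,140,5.696
male,250,145,5.357
male,250,150,5.056
male,250,155,4.787
male,250,160,4.545
male,250,165,4.327
male,250,170,4.128
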