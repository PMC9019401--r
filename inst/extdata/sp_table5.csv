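analyte,group,subject,value
SP-D,Con,1,8.558468
SP-D,COPD,1,28.2358871
SP-A,Con,1,10.66308
SP-A,COPD,1,18.30645
SP-D,Con,2,9.707661
SP-D,COPD,2,17.71169355
SP-A,Con,2,10.40323
SP-A,COPD,2,13.41398
SP-D,Con,3,21.13911
SP-D,COPD,3,69.81854839
SP-A,Con,3,10.98566
SP-A,COPD,3,66.33513
SP-D,Con,4,10.53427
SP-D,COPD,4,27.0766129
SP-A,Con,4,23.98746
SP-A,COPD,4,27.05197
SP-D,Con,5,22.06653
SP-D,COPD,5,13.61895161
SP-A,Con,5,12.06989
SP-A,COPD,5,11.36201
SP-D,Con,6,11.07863
SP-D,COPD,6,9.606854839
SP-A,Con,6,17.22222
SP-A,COPD,6,15.34213
SP-D,Con,7,11.5625
SP-D,COPD,7,18.40501792
SP-A,Con,7,15.83984
SP-A,COPD,7,12.36328
SP-D,Con,8,8.183594
SP-D,COPD,8,38.58359375
SP-A,Con,8,1.601563
SP-A,COPD,8,38.28125
SP-D,Con,9,0.214844
SP-D,COPD,9,35.3125
SP-A,Con,9,1.699219
SP-A,COPD,9,5.46875
SP-D,Con,10,0.234375
SP-D,COPD,10,5.2734375
SP-A,Con,10,14.16016
SP-A,COPD,10,49.02344
SP-D,Con,11,11.44531
SP-D,COPD,11,51.953125
SP-A,Con,11,11.30859
SP-A,COPD,11,11.89453
SP-D,Con,12,6.425781
SP-D,COPD,12,31.651135
SP-A,Con,12,7.673081
SP-A,COPD,12,17.10645
SP-D,Con,13,9.156457
SP-D,COPD,13,38.13558708
SP-A,Con,13,9.433126
SP-A,COPD,13,19.91498
SP-D,Con,14,6.502361
SP-D,COPD,14,47.51169335
SP-A,Con,14,5.915761
SP-A,COPD,14,69.13523
SP-D,Con,15,19.23321
SP-D,COPD,15,61.41154829
SP-A,Con,15,21.38143
SP-A,COPD,15,37.15297
SP-D,Con,16,11.33124
SP-D,COPD,16,29.9761129
SP-A,Con,16,12.31589
SP-A,COPD,16,31.16211
SP-D,Con,17,20.07523
SP-D,COPD,17,18.61716161
SP-A,Con,17,16.66722
SP-A,COPD,17,14.14216
SP-D,Con,18,13.17813
SP-D,COPD,18,29.00685484
SP-A,Con,18,14.77684
SP-A,COPD,18,32.16358
SP-D,Con,19,8.0645
SP-D,COPD,19,38.55050179
SP-A,Con,19,5.510567
SP-A,COPD,19,42.18127
SP-D,Con,20,12.18309
SP-D,COPD,20,28.48369315
SP-A,Con,20,7.641219
SP-A,COPD,20,35.56814
SP-D,Con,21,1.212254
SP-D,COPD,21,55.1167
SP-A,Con,21,10.24116
SP-A,COPD,21,59.42544
SP-D,Con,22,3.274585
SP-D,COPD,22,35.2754771
SP-A,Con,22,6.104774
SP-A,COPD,22,41.69353
SP-D,Con,23,14.43545
SP-D,COPD,23,59.157179
SP-A,Con,23,13.31659
SP-A,COPD,23,54.24117
SP-D,Con,24,4.445181
SP-D,COPD,24,37.154137
SP-A,Con,24,6.773082
SP-A,COPD,24,33.56458
SP-D,Con,25,8.930212
SP-D,COPD,25,29.174136
SP-A,Con,25,9.149126
SP-A,COPD,25,32.48224
SP-D,Con,26,18.55847
SP-D,COPD,26,38.5158851
SP-A,Con,26,20.66308
SP-A,COPD,26,48.80245
SP-D,Con,27,6.717564
SP-D,COPD,27,19.92364355
SP-A,Con,27,9.503526
SP-A,COPD,27,23.51318
SP-D,Con,28,20.63613
SP-D,COPD,28,65.41153839
SP-A,Con,28,16.18466
SP-A,COPD,28,65.12513
SP-D,Con,29,20.43428
SP-D,COPD,29,47.0911129
SP-A,Con,29,23.18145
SP-A,COPD,29,44.35127
SP-D,Con,30,12.06323
SP-D,COPD,30,23.11495168
SP-A,Con,30,12.76181
SP-A,COPD,30,31.56211
SP-D,Con,31,21.02842
SP-D,COPD,31,29.50285184
SP-A,Con,31,17.34567
SP-A,COPD,31,35.39116
SP-D,Con,32,12.1635
SP-D,COPD,32,28.10601795
SP-A,Con,32,15.72944
SP-A,COPD,32,22.34319
SP-D,Con,33,8.784514
SP-D,COPD,33,28.58152374
SP-A,Con,33,1.204512
SP-A,COPD,33,38.48027
SP-D,Con,34,0.894744
SP-D,COPD,34,11.51132581
SP-A,Con,34,0.662238
SP-A,COPD,34,15.56174
SP-D,Con,35,10.14732
SP-D,COPD,35,41.456112
SP-A,Con,35,11.79059
SP-A,COPD,35,31.09153
SP-D,Con,36,0.291324
SP-D,COPD,36,4.2974377
SP-A,Con,36,0.169157
SP-A,COPD,36,5.156138
SP-D,Con,37,17.13341
SP-D,COPD,37,64.41551829
SP-A,Con,37,21.98242
SP-A,COPD,37,67.45217
SP-D,Con,38,6.925581
SP-D,COPD,38,29.751336
SP-A,Con,38,7.875085
SP-A,COPD,38,31.00645
SP-D,Con,39,4.857157
SP-D,COPD,39,38.19658808
SP-A,Con,39,6.135127
SP-A,COPD,39,36.71597
SP-D,Con,40,6.912462
SP-D,COPD,40,49.42179236
SP-A,Con,40,5.516562
SP-A,COPD,40,55.57521
SP-D,Con,41,10.03727
SP-D,COPD,41,34.65609291
SP-A,Con,41,13.71881
SP-A,COPD,41,37.56976
SP-D,Con,42,16.98298
SP-D,COPD,42,28.67110678
SP-A,Con,42,13.11093
SP-A,COPD,42,24.5721
SP-D,Con,43,9.673159
SP-D,COPD,43,29.76651275
SP-A,Con,43,11.90128
SP-A,COPD,43,33.57092
SP-D,Con,44,18.0645
SP-D,COPD,44,38.75305505
SP-A,Con,44,5.997651
SP-A,COPD,44,43.59561
SP-D,Con,45,10.45172
SP-D,COPD,45,29.27614836
SP-A,Con,45,8.261964
SP-A,COPD,45,32.40166
SP-D,Con,46,0.891537
SP-D,COPD,46,15.29851164
SP-A,Con,46,1.860124
SP-A,COPD,46,19.73824
SP-D,Con,47,2.105975
SP-D,COPD,47,25.72642754
SP-A,Con,47,5.27501
SP-A,COPD,47,31.47027
SP-D,Con,48,12.72664
SP-D,COPD,48,59.772115
SP-A,Con,48,13.66063
SP-A,COPD,48,55.73892
SP-D,Con,49,4.697945
SP-D,COPD,49,38.002715
SP-A,Con,49,6.308153
SP-A,COPD,49,37.79076
SP-D,Con,50,8.159302
SP-D,COPD,50,29.708174
SP-A,Con,50,9.097149
SP-A,COPD,50,32.88905
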