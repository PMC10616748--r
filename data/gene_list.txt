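G0096
G0153
G0141
G0210
G0113
G0354
G0204
G0499
G0402
G0205
G0186
G0132
G0254
G0017
G0211
G0466
G0085
G0103
G0303
G0155
G0350
G0403
G0475
G0241
G0370
G0080
G0485
G0007
FAKE04
G0379
G0356
G0052
G0395
G0069
G0290
G0154
G0362
G0357
G0319
G0126
G0474
G0189
G0032
G0156
G0149
G0372
G0040
G0415
G0121
G0013
G0318
G0209
G0207
G0497
G0444
G0467
G0120
G0498
G0116
G0041
G0262
G0312
G0176
G0292
G0111
G0375
FAKE02
G0053
G0159
FAKE03
G0378
G0309
G0377
G0244
G0458
G0352
G0500
G0166
FAKE01
G0251
G0301
G0470
G0344
G0365
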