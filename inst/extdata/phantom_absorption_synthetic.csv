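"wavelength_nm","medium","pigment"
400,0.27002,0.386
402,0.26133,0.3856
404,0.253019,0.3852
406,0.245071,0.3848
408,0.23747,0.3844
410,0.230201,0.384
412,0.22325,0.3836
414,0.216603,0.3832
416,0.210249,0.3828
418,0.204174,0.3824
420,0.198367,0.382
422,0.192818,0.3816
424,0.187515,0.3812
426,0.182448,0.3808
428,0.177609,0.3804
430,0.172989,0.38
432,0.168578,0.3796
434,0.16437,0.3792
436,0.160357,0.3788
438,0.156532,0.3784
440,0.152889,0.378
442,0.149422,0.3776
444,0.146124,0.3772
446,0.142993,0.3768
448,0.140021,0.3764
450,0.137206,0.376
452,0.134544,0.3756
454,0.13203,0.3752
456,0.129663,0.3748
458,0.127439,0.3744
460,0.125356,0.374
462,0.123411,0.3736
464,0.121604,0.3732
466,0.119931,0.3728
468,0.118393,0.3724
470,0.116988,0.372
472,0.115715,0.3716
474,0.114572,0.3712
476,0.11356,0.3708
478,0.112677,0.3704
480,0.111923,0.37
482,0.111296,0.3696
484,0.110796,0.3692
486,0.110422,0.3688
488,0.110171,0.3684
490,0.110043,0.368
492,0.110035,0.3676
494,0.110145,0.3672
496,0.110371,0.3668
498,0.110708,0.3664
500,0.111153,0.366
502,0.111701,0.3656
504,0.112349,0.3652
506,0.113089,0.3648
508,0.113917,0.3644
510,0.114825,0.364
512,0.115806,0.3636
514,0.116851,0.3632
516,0.117953,0.3628
518,0.119102,0.3624
520,0.120289,0.362
522,0.121502,0.3616
524,0.122733,0.3612
526,0.12397,0.3608
528,0.125202,0.3604
530,0.126418,0.36
532,0.127606,0.3596
534,0.128755,0.3592
536,0.129855,0.3588
538,0.130893,0.3584
540,0.13186,0.358
542,0.132745,0.3576
544,0.133539,0.3572
546,0.134233,0.3568
548,0.134819,0.3564
550,0.135289,0.356
552,0.135637,0.3556
554,0.135857,0.3552
556,0.135945,0.3548
558,0.135898,0.3544
560,0.135713,0.354
562,0.13539,0.3536
564,0.134928,0.3532
566,0.134329,0.3528
568,0.133595,0.3524
570,0.132729,0.352
572,0.131736,0.3516
574,0.130621,0.3512
576,0.129391,0.3508
578,0.128052,0.3504
580,0.126613,0.35
582,0.125082,0.3496
584,0.123468,0.3492
586,0.12178,0.3488
588,0.120029,0.3484
590,0.118224,0.348
592,0.116375,0.3476
594,0.114492,0.3472
596,0.112586,0.3468
598,0.110665,0.3464
600,0.108741,0.346
602,0.10682,0.3456
604,0.104913,0.3452
606,0.103028,0.3448
608,0.101171,0.3444
610,0.0993507,0.344
612,0.0975724,0.3436
614,0.095842,0.3432
616,0.0941646,0.3428
618,0.0925444,0.3424
620,0.0909851,0.342
622,0.0894896,0.3416
624,0.0880601,0.3412
626,0.0866984,0.3408
628,0.0854054,0.3404
630,0.0841818,0.34
632,0.0830274,0.3396
634,0.0819417,0.3392
636,0.0809238,0.3388
638,0.0799724,0.3384
640,0.0790857,0.338
642,0.0782618,0.3376
644,0.0774985,0.3372
646,0.0767933,0.3368
648,0.0761436,0.3364
650,0.0755468,0.336
652,0.0749999,0.3356
654,0.0745002,0.3352
656,0.0740448,0.3348
658,0.0736307,0.3344
660,0.0732553,0.334
662,0.0729157,0.3336
664,0.0726093,0.3332
666,0.0723334,0.3328
668,0.0720856,0.3324
670,0.0718634,0.332
672,0.0716647,0.3316
674,0.0714872,0.3312
676,0.0713291,0.3308
678,0.0711884,0.3304
680,0.0710635,0.33
682,0.0709527,0.3296
684,0.0708545,0.3292
686,0.0707677,0.3288
688,0.0706909,0.3284
690,0.070623,0.328
692,0.0705631,0.3276
694,0.0705102,0.3272
696,0.0704635,0.3268
698,0.0704222,0.3264
700,0.0703858,0.326
702,0.0703535,0.3256
704,0.0703249,0.3252
706,0.0702995,0.3248
708,0.070277,0.3244
710,0.0702568,0.324
712,0.0702389,0.3236
714,0.0702227,0.3232
716,0.0702082,0.3228
718,0.0701952,0.3224
720,0.0701833,0.322
722,0.0701726,0.3216
724,0.0701627,0.3212
726,0.0701537,0.3208
728,0.0701455,0.3204
730,0.0701379,0.32
732,0.0701308,0.3196
734,0.0701242,0.3192
736,0.0701181,0.3188
738,0.0701124,0.3184
740,0.070107,0.318
742,0.070102,0.3176
744,0.0700973,0.3172
746,0.0700928,0.3168
748,0.0700886,0.3164
750,0.0700845,0.316
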