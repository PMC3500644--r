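minutes,exam,t1_myo,t1_blood,lambda
0,1,1011,1526,NA
5,1,301,148,0.382
10,1,353,199,0.420
15,1,389,255,0.416
20,1,411,246,0.423
25,1,432,265,0.424
30,1,450,283,0.426
35,1,465,300,0.434
40,1,475,315,0.442
45,1,488,329,0.444
50,1,502,344,0.446
55,1,513,358,0.449
60,1,524,373,0.454
0,2,1002,1547,NA
5,2,308,155,0.386
10,2,367,206,0.410
15,2,367,234,0.409
20,2,403,253,0.411
25,2,425,272,0.411
30,2,445,290,0.419
35,2,460,306,0.428
40,2,479,321,0.440
45,2,500,338,0.432
50,2,509,351,0.440
55,2,525,364,0.431
60,2,537,379,0.432
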