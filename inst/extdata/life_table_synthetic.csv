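age,sex,qx
0,male,0.004929
1,male,0.000932
2,male,0.000935
3,male,0.000939
4,male,0.000943
5,male,0.000948
6,male,0.000953
7,male,0.000958
8,male,0.000964
9,male,0.000971
10,male,0.000978
11,male,0.000986
12,male,0.000995
13,male,0.001005
14,male,0.001015
15,male,0.001027
16,male,0.001041
17,male,0.001055
18,male,0.001071
19,male,0.001089
20,male,0.001108
21,male,0.00113
22,male,0.001153
23,male,0.00118
24,male,0.001208
25,male,0.00124
26,male,0.001275
27,male,0.001314
28,male,0.001356
29,male,0.001404
30,male,0.001455
31,male,0.001513
32,male,0.001576
33,male,0.001645
34,male,0.001722
35,male,0.001807
36,male,0.0019
37,male,0.002003
38,male,0.002116
39,male,0.002242
40,male,0.00238
41,male,0.002532
42,male,0.0027
43,male,0.002885
44,male,0.003089
45,male,0.003315
46,male,0.003563
47,male,0.003837
48,male,0.004139
49,male,0.004472
50,male,0.004839
51,male,0.005243
52,male,0.005689
53,male,0.006181
54,male,0.006724
55,male,0.007321
56,male,0.00798
57,male,0.008706
58,male,0.009507
59,male,0.010389
60,male,0.011361
61,male,0.012431
62,male,0.013611
63,male,0.014911
64,male,0.016342
65,male,0.017919
66,male,0.019654
67,male,0.021565
68,male,0.023669
69,male,0.025983
70,male,0.02853
71,male,0.031331
72,male,0.034411
73,male,0.037797
74,male,0.041518
75,male,0.045606
76,male,0.050094
77,male,0.055019
78,male,0.060422
79,male,0.066346
80,male,0.072836
81,male,0.079942
82,male,0.087717
83,male,0.096216
84,male,0.105498
85,male,0.115625
86,male,0.126662
87,male,0.138676
88,male,0.151736
89,male,0.16591
90,male,0.18127
91,male,0.197883
92,male,0.215816
93,male,0.23513
94,male,0.255883
95,male,0.278119
96,male,0.301875
97,male,0.327172
98,male,0.354011
99,male,0.382374
100,male,1
0,female,0.003411
1,female,0.000413
2,female,0.000414
3,female,0.000416
4,female,0.000417
5,female,0.000419
6,female,0.000422
7,female,0.000424
8,female,0.000427
9,female,0.00043
10,female,0.000433
11,female,0.000436
12,female,0.000441
13,female,0.000445
14,female,0.00045
15,female,0.000456
16,female,0.000462
17,female,0.000469
18,female,0.000476
19,female,0.000485
20,female,0.000494
21,female,0.000504
22,female,0.000516
23,female,0.000529
24,female,0.000543
25,female,0.000559
26,female,0.000576
27,female,0.000596
28,female,0.000618
29,female,0.000642
30,female,0.000669
31,female,0.000698
32,female,0.000731
33,female,0.000768
34,female,0.000809
35,female,0.000854
36,female,0.000904
37,female,0.00096
38,female,0.001022
39,female,0.001091
40,female,0.001167
41,female,0.001252
42,female,0.001347
43,female,0.001451
44,female,0.001568
45,female,0.001697
46,female,0.00184
47,female,0.002
48,female,0.002177
49,female,0.002373
50,female,0.002591
51,female,0.002834
52,female,0.003103
53,female,0.003401
54,female,0.003733
55,female,0.004101
56,female,0.00451
57,female,0.004964
58,female,0.005469
59,female,0.006028
60,female,0.006649
61,female,0.007339
62,female,0.008104
63,female,0.008953
64,female,0.009896
65,female,0.010941
66,female,0.012101
67,female,0.013389
68,female,0.014816
69,female,0.016399
70,female,0.018155
71,female,0.020101
72,female,0.022258
73,female,0.024648
74,female,0.027296
75,female,0.030229
76,female,0.033477
77,female,0.03707
78,female,0.041047
79,female,0.045444
80,female,0.050304
81,female,0.055674
82,female,0.061602
83,female,0.068143
84,female,0.075355
85,female,0.083299
86,female,0.092044
87,female,0.101658
88,female,0.112218
89,female,0.123802
90,female,0.136491
91,female,0.150369
92,female,0.165522
93,female,0.182037
94,female,0.199997
95,female,0.219483
96,female,0.240571
97,female,0.263327
98,female,0.287803
99,female,0.314037
100,female,1
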