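16.024
9.732
1.234
3.435
19.930
17.338
3.504
16.964
2.920
18.585
3.557
17.855
27.658
19.529
20.221
21.283
51.591
10.020
8.746
4.123
58.936
2.139
4.177
17.134
8.536
28.781
3.683
5.600
3.708
10.596
0.151
1.549
14.906
5.498
15.177
34.176
6.523
18.555
7.559
13.495
38.822
48.647
13.066
8.653
11.862
70.155
1.656
34.555
16.042
15.488
7.648
44.206
21.384
11.119
37.804
62.485
4.267
12.572
10.306
7.246
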