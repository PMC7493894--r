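time,response,label
0,94.474,PC9-TM
4.545,88.2824,PC9-TM
9.091,80.6784,PC9-TM
13.636,75.0566,PC9-TM
18.182,71.9957,PC9-TM
22.727,65.1961,PC9-TM
27.273,62.6588,PC9-TM
31.818,57.8346,PC9-TM
36.364,53.3536,PC9-TM
40.909,48.9108,PC9-TM
45.455,45.7492,PC9-TM
50,43.1099,PC9-TM
54.545,39.2165,PC9-TM
59.091,37.7384,PC9-TM
63.636,34.5212,PC9-TM
68.182,33.3178,PC9-TM
72.727,31.04,PC9-TM
77.273,30.1169,PC9-TM
81.818,27.0329,PC9-TM
86.364,25.3433,PC9-TM
90.909,23.8101,PC9-TM
95.455,23.0084,PC9-TM
100,21.3392,PC9-TM
104.545,20.8552,PC9-TM
109.091,19.5051,PC9-TM
113.636,18.4284,PC9-TM
118.182,17.3141,PC9-TM
122.727,15.93,PC9-TM
127.273,15.611,PC9-TM
131.818,14.1894,PC9-TM
136.364,13.3954,PC9-TM
140.909,12.9087,PC9-TM
145.455,13.761,PC9-TM
150,11.211,PC9-TM
154.545,11.3397,PC9-TM
159.091,12.0822,PC9-TM
163.636,11.0572,PC9-TM
168.182,12.2027,PC9-TM
172.727,9.9174,PC9-TM
177.273,9.8141,PC9-TM
181.818,8.3548,PC9-TM
186.364,9.5407,PC9-TM
190.909,10.0494,PC9-TM
195.455,8.2324,PC9-TM
200,9.5734,PC9-TM
0,86.7711,PC9-WT
2.841,83.0223,PC9-WT
5.682,75.1085,PC9-WT
8.523,69.7685,PC9-WT
11.364,63.9104,PC9-WT
14.205,60.7547,PC9-WT
17.045,56.4787,PC9-WT
19.886,52.3,PC9-WT
22.727,49.1108,PC9-WT
25.568,46.2066,PC9-WT
28.409,42.1116,PC9-WT
31.25,38.8233,PC9-WT
34.091,36.6069,PC9-WT
36.932,34.8208,PC9-WT
39.773,32.4264,PC9-WT
42.614,29.882,PC9-WT
45.455,29.5238,PC9-WT
48.295,27.0368,PC9-WT
51.136,25.5272,PC9-WT
53.977,23.34,PC9-WT
56.818,22.3615,PC9-WT
59.659,22.5409,PC9-WT
62.5,20.5124,PC9-WT
65.341,18.3101,PC9-WT
68.182,16.683,PC9-WT
71.023,16.3626,PC9-WT
73.864,15.5418,PC9-WT
76.705,15.0049,PC9-WT
79.545,14.2675,PC9-WT
82.386,13.7542,PC9-WT
85.227,13.3728,PC9-WT
88.068,13.9414,PC9-WT
90.909,11.2255,PC9-WT
93.75,10.2805,PC9-WT
96.591,10.3926,PC9-WT
99.432,9.8672,PC9-WT
102.273,10.0988,PC9-WT
105.114,9.1038,PC9-WT
107.955,9.8232,PC9-WT
110.795,8.0119,PC9-WT
113.636,8.6415,PC9-WT
116.477,7.3257,PC9-WT
119.318,8.5161,PC9-WT
122.159,6.4819,PC9-WT
125,7.3377,PC9-WT
0,70.3659,PC9-F404D
1.136,64.8159,PC9-F404D
2.273,61.552,PC9-F404D
3.409,56.2335,PC9-F404D
4.545,52.9169,PC9-F404D
5.682,48.789,PC9-F404D
6.818,45.9545,PC9-F404D
7.955,42.1829,PC9-F404D
9.091,38.9052,PC9-F404D
10.227,37.2136,PC9-F404D
11.364,33.3019,PC9-F404D
12.5,32.0544,PC9-F404D
13.636,28.7495,PC9-F404D
14.773,26.4801,PC9-F404D
15.909,25.6192,PC9-F404D
17.045,24.122,PC9-F404D
18.182,23.6378,PC9-F404D
19.318,21.3649,PC9-F404D
20.455,19.9127,PC9-F404D
21.591,19.2407,PC9-F404D
22.727,17.8312,PC9-F404D
23.864,17.8353,PC9-F404D
25,15.9031,PC9-F404D
26.136,14.0936,PC9-F404D
27.273,14.3761,PC9-F404D
28.409,13.3104,PC9-F404D
29.545,11.5509,PC9-F404D
30.682,10.5313,PC9-F404D
31.818,10.5755,PC9-F404D
32.955,10.2417,PC9-F404D
34.091,10.2076,PC9-F404D
35.227,10.302,PC9-F404D
36.364,9.0544,PC9-F404D
37.5,8.558,PC9-F404D
38.636,8.3536,PC9-F404D
39.773,7.7907,PC9-F404D
40.909,7.6534,PC9-F404D
42.045,7.4203,PC9-F404D
43.182,6.7391,PC9-F404D
44.318,6.499,PC9-F404D
45.455,6.8926,PC9-F404D
46.591,7.6617,PC9-F404D
47.727,6.7883,PC9-F404D
48.864,7.2971,PC9-F404D
50,5.7532,PC9-F404D
0,54.6558,C9-35/12
0.455,51.9551,C9-35/12
0.909,48.5242,C9-35/12
1.364,44.8348,C9-35/12
1.818,40.9277,C9-35/12
2.273,38.7129,C9-35/12
2.727,35.382,C9-35/12
3.182,33.5163,C9-35/12
3.636,30.495,C9-35/12
4.091,29.1361,C9-35/12
4.545,26.456,C9-35/12
5,25.019,C9-35/12
5.455,23.5579,C9-35/12
5.909,21.5244,C9-35/12
6.364,20.5158,C9-35/12
6.818,19.4136,C9-35/12
7.273,18.7147,C9-35/12
7.727,17.4672,C9-35/12
8.182,15.6672,C9-35/12
8.636,15.2085,C9-35/12
9.091,13.102,C9-35/12
9.545,12.8425,C9-35/12
10,12.2646,C9-35/12
10.455,11.3509,C9-35/12
10.909,11.2212,C9-35/12
11.364,9.8592,C9-35/12
11.818,10.4586,C9-35/12
12.273,9.6393,C9-35/12
12.727,8.5227,C9-35/12
13.182,7.5539,C9-35/12
13.636,7.1557,C9-35/12
14.091,7.3537,C9-35/12
14.545,7.3296,C9-35/12
15,7.239,C9-35/12
15.455,6.797,C9-35/12
15.909,6.1186,C9-35/12
16.364,6.2063,C9-35/12
16.818,5.6844,C9-35/12
17.273,6.2873,C9-35/12
17.727,5.4176,C9-35/12
18.182,5.0026,C9-35/12
18.636,5.257,C9-35/12
19.091,4.9236,C9-35/12
19.545,4.7274,C9-35/12
20,3.9509,C9-35/12
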