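rank,score
1,35.40
2,18.89
3,15.28
4,13.97
5,10.82
6,10.70
7,10.46
8,10.31
9,10.05
10,8.79
11,7.79
12,7.49
13,7.30
14,7.10
15,6.77
16,6.42
17,6.15
18,6.06
19,5.69
20,4.88
21,4.75
22,4.55
23,4.01
24,3.93
25,3.14
26,2.86
27,1.82
28,1.54
29,0.95
30,0.83
31,0.65
32,0.62
33,0.46
34,0.44
35,0.33
36,0.10
37,0.08
38,-0.32
39,-0.34
40,-0.41
41,-0.52
42,-0.53
43,-0.63
44,-0.65
45,-0.66
46,-0.72
47,-0.78
48,-1.02
49,-1.05
50,-1.17
51,-1.44
52,-1.70
53,-1.78
54,-1.83
55,-1.99
56,-2.06
57,-2.17
58,-2.18
59,-2.42
60,-2.52
61,-2.54
62,-2.73
63,-2.84
64,-2.92
65,-2.97
66,-3.06
67,-3.15
68,-3.67
69,-4.09
70,-4.26
71,-4.49
72,-4.89
73,-5.55
74,-5.99
75,-6.60
76,-6.78
77,-7.06
78,-7.16
79,-7.71
80,-7.97
81,-8.41
82,-9.37
83,-9.46
84,-9.57
85,-10.26
86,-10.45
87,-13.84
88,-14.19
89,-14.67
90,-15.83
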