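from,to
1,2
2,3
2,31
1,4
1,32
4,5
5,6
6,7
7,4
32,33
33,34
34,35
35,32
6,8
34,37
8,9
9,10
10,11
11,8
37,38
3,30
31,30
30,9
30,37
9,12
37,40
12,19
40,47
19,13
47,41
13,14
14,15
15,16
16,13
41,42
10,24
38,52
24,13
52,41
14,20
20,22
22,23
42,51
25,26
26,27
27,28
28,25
53,54
54,55
55,56
56,53
29,26
29,54
12,25
40,53
27,23
55,51
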