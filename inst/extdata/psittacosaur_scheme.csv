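id,description,pair,midline,excluded
1,Ventral tip of the rostral on midline,NA,TRUE,FALSE
2,Dorsalmost part of rostralmost nasal on midline,NA,TRUE,FALSE
3,Height of right nasal on skull roof,31,FALSE,FALSE
4,Rostral position of right naris (middle),32,FALSE,FALSE
5,Dorsal position of right naris (middle),33,FALSE,FALSE
6,Caudal position of right naris (middle),34,FALSE,FALSE
7,Ventral position of right naris (middle),35,FALSE,FALSE
8,Rostral position of right orbit (middle),36,FALSE,FALSE
9,Dorsal position of right orbit (middle),37,FALSE,FALSE
10,Caudal position of right orbit (middle),38,FALSE,FALSE
11,Ventral position of right orbit (middle),39,FALSE,FALSE
12,Height of right postorbital,40,FALSE,FALSE
13,Rostral position of right lateral temporal fenestra (middle),41,FALSE,FALSE
14,Dorsal position of right lateral temporal fenestra (middle),42,FALSE,FALSE
15,Caudal position of right lateral temporal fenestra (middle),43,FALSE,FALSE
16,Ventral position of right lateral temporal fenestra (middle),44,FALSE,FALSE
17,Right jugal region (approximate label),45,FALSE,TRUE
18,Right quadratojugal region (approximate label),46,FALSE,TRUE
19,Postorbital eminence (right),47,FALSE,FALSE
20,Dorsal position of right quadrate,48,FALSE,FALSE
21,Ventral position of right quadrate (approximate label),49,FALSE,TRUE
22,Middle of right quadrate on caudal aspect,50,FALSE,FALSE
23,Height of right side of skull on caudalmost point (squamosal),51,FALSE,FALSE
24,Lateralmost point of right jugal horn,52,FALSE,FALSE
25,Rostral position of right supratemporal fenestra (middle),53,FALSE,FALSE
26,Medial position of right supratemporal fenestra (middle),54,FALSE,FALSE
27,Caudal position of right supratemporal fenestra (middle),55,FALSE,FALSE
28,Lateral position of right supratemporal fenestra (middle),56,FALSE,FALSE
29,Sagittal crest at middle of supratemporal fenestrae,NA,TRUE,FALSE
30,Frontal suture at middle of orbit,NA,TRUE,FALSE
31,Height of left nasal on skull roof,3,FALSE,FALSE
32,Rostral position of left naris (middle),4,FALSE,FALSE
33,Dorsal position of left naris (middle),5,FALSE,FALSE
34,Caudal position of left naris (middle),6,FALSE,FALSE
35,Ventral position of left naris (middle),7,FALSE,FALSE
36,Rostral position of left orbit (middle),8,FALSE,TRUE
37,Dorsal position of left orbit (middle),9,FALSE,FALSE
38,Caudal position of left orbit (middle),10,FALSE,FALSE
39,Ventral position of left orbit (middle),11,FALSE,TRUE
40,Height of left postorbital,12,FALSE,FALSE
41,Rostral position of left lateral temporal fenestra (middle),13,FALSE,FALSE
42,Dorsal position of left lateral temporal fenestra (middle),14,FALSE,FALSE
43,Caudal position of left lateral temporal fenestra (middle),15,FALSE,TRUE
44,Ventral position of left lateral temporal fenestra (middle),16,FALSE,TRUE
45,Left jugal region (approximate label),17,FALSE,TRUE
46,Left quadratojugal region (approximate label),18,FALSE,TRUE
47,Postorbital eminence (left),19,FALSE,FALSE
48,Dorsal position of left quadrate,20,FALSE,TRUE
49,Ventral position of left quadrate (approximate label),21,FALSE,TRUE
50,Middle of left quadrate on caudal aspect,22,FALSE,TRUE
51,Height of left side of skull on caudalmost point (squamosal),23,FALSE,FALSE
52,Lateralmost point of left jugal horn,24,FALSE,FALSE
53,Rostral position of left supratemporal fenestra (middle),25,FALSE,FALSE
54,Medial position of left supratemporal fenestra (middle),26,FALSE,FALSE
55,Caudal position of left supratemporal fenestra (middle),27,FALSE,FALSE
56,Lateral position of left supratemporal fenestra (middle),28,FALSE,FALSE
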