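case,n,hull_volume
1,11,0.217520761673183
2,12,0.170999688388702
3,13,0.160929981177172
4,14,0.265534787280252
5,15,0.222294112903273
6,16,0.33976635927405
7,17,0.292681000202488
8,18,0.230438593045404
9,19,0.251779963077435
10,20,0.341472109716461
11,21,0.27198552248977
12,22,0.378783872726198
13,23,0.39296081869491
14,24,0.297542569306611
15,25,0.323613319063445
16,26,0.415310633628481
17,27,0.393745420568402
18,28,0.442019581295109
19,29,0.462332234499219
20,10,0.187221452089057
21,11,0.260263726406027
22,12,0.26135731052482
23,13,0.238517225284506
24,14,0.279018553928061
25,15,0.200866223157366
26,16,0.228369011857958
27,17,0.278455170889429
28,18,0.452213248506297
29,19,0.284516644572853
30,20,0.30213290069888
31,21,0.241074186954256
32,22,0.38430817345151
33,23,0.267262432361887
34,24,0.468312449336936
35,25,0.405152420124227
36,26,0.336442365924493
37,27,0.294249633853406
38,28,0.566104527218361
39,29,0.442825518735802
40,10,0.24652848170106
41,11,0.194843494033032
42,12,0.15619039392031
43,13,0.276433091381053
44,14,0.208606275632905
45,15,0.227696896895042
46,16,0.253145536944496
47,17,0.234391536303041
48,18,0.394473140800361
49,19,0.252069450979699
50,20,0.287329095232391
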