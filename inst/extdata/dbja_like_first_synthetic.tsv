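# experiment: dbja_like_synthetic
# protein: DbjA-like (synthetic)
# role: first
# scan_rate_C_per_min: 1
# temp_unit: celsius
# cp_unit: kJ
20.0	34.3619853576114
20.5	34.6957984649107
21.0	33.9492252391042
21.5	34.0511758045330
22.0	35.3467479985825
22.5	34.3154290403649
23.0	35.4693092602338
23.5	35.1449676864120
24.0	34.8346505003075
24.5	34.3804559978814
25.0	34.4933054821768
25.5	34.7583540769462
26.0	34.1883937951309
26.5	34.8547720623294
27.0	34.4326012266229
27.5	35.0387627880486
28.0	34.9461487751979
28.5	35.5265651826468
29.0	34.8116629403550
29.5	34.8049632359917
30.0	34.8166724240630
30.5	35.1751472049383
31.0	34.9869668585271
31.5	35.4098043476877
32.0	35.2954510786333
32.5	35.2878961380796
33.0	35.2161137949455
33.5	34.9528533093873
34.0	35.2512187072740
34.5	34.8963300261948
35.0	34.8627980018993
35.5	34.9732561992826
36.0	35.8097894334341
36.5	34.7108629685262
37.0	35.0950708256804
37.5	35.8044975911983
38.0	35.5034595917719
38.5	36.4064700467537
39.0	35.3689618436667
39.5	35.5466168033669
40.0	34.9544297013216
40.5	35.8433169154427
41.0	36.3501303823291
41.5	35.5528700561750
42.0	36.5371757815278
42.5	36.0462638899567
43.0	35.2807062220660
43.5	37.0084346372386
44.0	37.1739771077553
44.5	37.2288234423966
45.0	37.9014188175311
45.5	37.8818464292704
46.0	38.2082167964021
46.5	39.6522024004582
47.0	40.4725246547765
47.5	41.9103885186134
48.0	43.1209884328031
48.5	45.3596726022014
49.0	48.2783224674729
49.5	50.4847434048970
50.0	53.5406441255002
50.5	59.2749494604328
51.0	62.8042901244211
51.5	67.1774835536676
52.0	74.0218798484332
52.5	80.1293346180070
53.0	83.7704948864543
53.5	87.1079453083475
54.0	88.5741899318986
54.5	87.5177237413892
55.0	82.3653499287399
55.5	74.2586396852756
56.0	64.6071671818888
56.5	56.1084439641765
57.0	49.5615648502605
57.5	44.8091116218890
58.0	42.4275665177051
58.5	42.3709402541373
59.0	41.4937165244211
59.5	42.2346404216771
60.0	42.0251568468054
60.5	42.2402486973784
61.0	41.8046592248400
61.5	41.6787076542110
62.0	43.2883044878911
62.5	41.8808866459004
63.0	41.5585689521964
63.5	42.4857256013819
64.0	41.8308328688057
64.5	41.5294841053258
65.0	42.9086644496963
65.5	41.8185673071377
66.0	42.8266349788925
66.5	42.1109226707932
67.0	42.6640475625303
67.5	42.2562045587404
68.0	43.1207666433026
68.5	41.9124240763125
69.0	43.2140549689797
69.5	42.2314106080724
70.0	42.3366656905695
70.5	42.7043193864909
71.0	42.9058905757761
71.5	42.5724796430105
72.0	41.6226282618800
72.5	42.9753127926702
73.0	42.9521957101474
73.5	42.2292018529047
74.0	43.3923266454036
74.5	43.3444578606212
75.0	43.2287418815677
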