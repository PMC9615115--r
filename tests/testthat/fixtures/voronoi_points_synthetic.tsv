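"x"	"y"	"z"
2.875775	1.428	2.436195
7.883051	4.145463	6.680556
4.089769	4.137243	4.176468
8.830174	3.688455	7.881958
9.404673	1.524447	1.028646
0.455565	1.388061	4.348927
5.281055	2.330341	9.84957
8.92419	4.659625	8.930511
5.51435	2.659726	8.864691
4.566147	8.578277	1.750527
9.568333	0.458312	1.306957
4.533342	4.422001	6.531019
6.775706	7.989248	3.435165
5.726334	1.218993	6.567581
1.029247	5.60948	3.203732
8.99825	2.065314	1.876911
2.460877	1.275317	7.822943
0.420595	7.533079	0.93595
3.279207	8.950454	4.66779
9.545036	3.744628	5.115055
8.895393	6.651152	5.99989
6.928034	0.948407	3.328235
6.405068	3.839696	4.88613
9.942698	2.743836	9.544738
6.557058	8.1464	4.829024
7.085305	4.485163	8.903502
5.44066	8.100644	9.144382
5.94142	8.123895	6.08735
2.891597	7.943423	4.106898
1.471136	4.398317	1.470947
9.630242	7.544752	9.352998
9.02299	6.292211	3.012289
6.907053	7.101824	0.607206
7.954674	0.006248	9.477269
0.246137	4.753166	7.205963
4.77796	2.201189	1.422943
7.584595	3.798165	5.492847
2.164079	6.12771	9.540912
3.18181	3.517979	5.854834
2.316258	1.111354	4.045103
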