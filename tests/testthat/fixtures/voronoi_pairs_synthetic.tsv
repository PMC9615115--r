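i	j
1	3
1	5
1	6
1	10
1	11
1	16
1	17
1	18
1	19
1	22
1	24
1	29
1	30
1	36
1	40
2	4
2	8
2	9
2	12
2	14
2	20
2	21
2	23
2	26
2	28
2	35
2	37
3	10
3	12
3	13
3	14
3	15
3	22
3	23
3	25
3	28
3	29
3	30
3	33
3	36
3	38
3	39
3	40
4	6
4	8
4	9
4	14
4	17
4	20
4	24
4	26
4	34
4	35
4	37
5	6
5	7
5	9
5	11
5	16
5	17
5	24
5	26
5	30
5	34
6	11
6	13
6	14
6	15
6	16
6	17
6	18
6	19
6	20
6	21
6	22
6	25
6	29
6	30
6	31
6	32
6	34
6	37
6	39
6	40
7	9
7	10
7	14
7	16
7	17
7	22
7	26
7	27
7	30
7	33
7	34
7	36
7	38
8	16
8	18
8	21
8	24
8	26
8	30
8	31
8	32
8	33
8	35
8	38
9	12
9	14
9	17
9	24
9	26
9	27
9	34
9	38
9	39
10	13
10	15
10	17
10	18
10	19
10	22
10	27
10	29
10	30
10	33
10	34
10	36
10	38
11	13
11	16
11	17
11	18
11	22
11	24
11	29
11	31
11	32
11	33
11	34
11	40
12	14
12	17
12	19
12	23
12	25
12	26
12	27
12	28
12	29
12	35
12	38
12	39
13	18
13	19
13	21
13	22
13	23
13	25
13	29
13	32
13	33
13	34
14	17
14	19
14	22
14	23
14	25
14	27
14	28
14	34
14	37
14	39
14	40
15	16
15	18
15	20
15	21
15	29
15	30
15	32
15	35
15	38
15	39
15	40
16	20
16	22
16	23
16	24
16	26
16	30
16	32
16	34
16	36
16	37
17	18
17	19
17	20
17	21
17	24
17	27
17	28
17	30
17	31
17	34
17	35
17	36
17	38
17	39
17	40
18	29
18	30
18	31
18	32
18	33
18	34
18	38
19	21
19	22
19	25
19	27
19	28
19	29
19	31
19	38
19	40
20	21
20	22
20	30
20	32
20	35
20	37
20	39
21	23
21	25
21	26
21	27
21	28
21	29
21	31
21	32
21	33
21	34
21	35
21	37
21	38
22	23
22	25
22	34
22	36
22	37
22	40
23	25
23	26
23	28
23	32
23	33
23	36
23	37
23	39
24	26
24	30
24	34
24	35
24	38
25	28
25	29
25	32
25	34
26	27
26	28
26	31
26	32
26	33
26	36
26	38
27	28
27	31
27	33
27	34
27	38
28	29
28	31
28	34
28	38
29	32
29	35
29	38
29	39
29	40
30	32
30	36
30	38
30	40
31	33
31	34
31	35
31	38
32	33
32	37
33	34
33	36
33	38
34	36
35	38
35	39
36	38
38	39
39	40
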