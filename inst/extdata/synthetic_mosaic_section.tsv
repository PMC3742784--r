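position	label	topology	p	p_source
1	-	linear	0.5	supplied
2	-	linear	0.5	supplied
3	-	linear	0.5	supplied
4	-	linear	0.5	supplied
5	-	linear	0.5	supplied
6	-	linear	0.5	supplied
7	+	linear	0.5	supplied
8	+	linear	0.5	supplied
9	+	linear	0.5	supplied
10	+	linear	0.5	supplied
11	+	linear	0.5	supplied
12	+	linear	0.5	supplied
13	+	linear	0.5	supplied
14	+	linear	0.5	supplied
15	+	linear	0.5	supplied
16	+	linear	0.5	supplied
17	+	linear	0.5	supplied
18	+	linear	0.5	supplied
19	+	linear	0.5	supplied
20	+	linear	0.5	supplied
21	+	linear	0.5	supplied
22	+	linear	0.5	supplied
23	-	linear	0.5	supplied
24	+	linear	0.5	supplied
25	+	linear	0.5	supplied
26	+	linear	0.5	supplied
27	+	linear	0.5	supplied
28	+	linear	0.5	supplied
29	+	linear	0.5	supplied
30	+	linear	0.5	supplied
31	+	linear	0.5	supplied
32	+	linear	0.5	supplied
33	+	linear	0.5	supplied
34	+	linear	0.5	supplied
35	+	linear	0.5	supplied
36	-	linear	0.5	supplied
37	-	linear	0.5	supplied
38	+	linear	0.5	supplied
39	+	linear	0.5	supplied
40	-	linear	0.5	supplied
41	-	linear	0.5	supplied
42	-	linear	0.5	supplied
43	-	linear	0.5	supplied
44	-	linear	0.5	supplied
45	-	linear	0.5	supplied
46	-	linear	0.5	supplied
47	-	linear	0.5	supplied
48	-	linear	0.5	supplied
49	-	linear	0.5	supplied
50	-	linear	0.5	supplied
51	-	linear	0.5	supplied
52	-	linear	0.5	supplied
53	-	linear	0.5	supplied
54	-	linear	0.5	supplied
55	-	linear	0.5	supplied
56	-	linear	0.5	supplied
57	-	linear	0.5	supplied
58	-	linear	0.5	supplied
59	-	linear	0.5	supplied
60	-	linear	0.5	supplied
61	-	linear	0.5	supplied
62	-	linear	0.5	supplied
63	-	linear	0.5	supplied
64	-	linear	0.5	supplied
65	-	linear	0.5	supplied
66	-	linear	0.5	supplied
67	-	linear	0.5	supplied
68	+	linear	0.5	supplied
69	+	linear	0.5	supplied
70	+	linear	0.5	supplied
71	-	linear	0.5	supplied
72	-	linear	0.5	supplied
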