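id	composition
1	HexNAc(2)Hex(1)
2	HexNAc(2)Hex(2)
3	HexNAc(2)Hex(3)
4	HexNAc(2)Hex(4)
5	HexNAc(2)Hex(5)
6	HexNAc(2)Hex(6)
7	HexNAc(2)Hex(7)
8	HexNAc(2)Hex(8)
9	HexNAc(2)Hex(9)
10	HexNAc(2)Hex(10)
11	HexNAc(2)Hex(11)
12	HexNAc(2)Hex(12)
13	HexNAc(2)Hex(1)Fuc(1)
14	HexNAc(2)Hex(2)Fuc(1)
15	HexNAc(2)Hex(3)Fuc(1)
16	HexNAc(2)Hex(4)Fuc(1)
17	HexNAc(2)Hex(5)Fuc(1)
18	HexNAc(2)Hex(6)Fuc(1)
19	HexNAc(2)Hex(7)Fuc(1)
20	HexNAc(2)Hex(5)Phospho(1)
21	HexNAc(2)Hex(6)Phospho(1)
22	HexNAc(2)Hex(7)Phospho(1)
23	HexNAc(2)Hex(8)Phospho(1)
24	HexNAc(2)Hex(9)Phospho(1)
25	HexNAc(3)Hex(3)
26	HexNAc(3)Hex(4)
27	HexNAc(3)Hex(5)
28	HexNAc(3)Hex(6)
29	HexNAc(3)Hex(7)
30	HexNAc(4)Hex(3)
31	HexNAc(4)Hex(4)
32	HexNAc(4)Hex(5)
33	HexNAc(4)Hex(6)
34	HexNAc(4)Hex(7)
35	HexNAc(5)Hex(3)
36	HexNAc(5)Hex(4)
37	HexNAc(5)Hex(5)
38	HexNAc(5)Hex(6)
39	HexNAc(5)Hex(7)
40	HexNAc(6)Hex(3)
41	HexNAc(6)Hex(4)
42	HexNAc(6)Hex(5)
43	HexNAc(6)Hex(6)
44	HexNAc(6)Hex(7)
45	HexNAc(3)Hex(3)Fuc(1)
46	HexNAc(3)Hex(4)Fuc(1)
47	HexNAc(3)Hex(5)Fuc(1)
48	HexNAc(3)Hex(6)Fuc(1)
49	HexNAc(3)Hex(7)Fuc(1)
50	HexNAc(4)Hex(3)Fuc(1)
51	HexNAc(4)Hex(4)Fuc(1)
52	HexNAc(4)Hex(5)Fuc(1)
53	HexNAc(4)Hex(6)Fuc(1)
54	HexNAc(4)Hex(7)Fuc(1)
55	HexNAc(5)Hex(3)Fuc(1)
56	HexNAc(5)Hex(4)Fuc(1)
57	HexNAc(5)Hex(5)Fuc(1)
58	HexNAc(5)Hex(6)Fuc(1)
59	HexNAc(5)Hex(7)Fuc(1)
60	HexNAc(6)Hex(3)Fuc(1)
61	HexNAc(6)Hex(4)Fuc(1)
62	HexNAc(6)Hex(5)Fuc(1)
63	HexNAc(6)Hex(6)Fuc(1)
64	HexNAc(6)Hex(7)Fuc(1)
65	HexNAc(3)Hex(4)NeuAc(1)
66	HexNAc(3)Hex(4)NeuAc(2)
67	HexNAc(3)Hex(5)NeuAc(1)
68	HexNAc(3)Hex(5)NeuAc(2)
69	HexNAc(3)Hex(6)NeuAc(1)
70	HexNAc(3)Hex(6)NeuAc(2)
71	HexNAc(4)Hex(4)NeuAc(1)
72	HexNAc(4)Hex(4)NeuAc(2)
73	HexNAc(4)Hex(5)NeuAc(1)
74	HexNAc(4)Hex(5)NeuAc(2)
75	HexNAc(4)Hex(6)NeuAc(1)
76	HexNAc(4)Hex(6)NeuAc(2)
77	HexNAc(5)Hex(4)NeuAc(1)
78	HexNAc(5)Hex(4)NeuAc(2)
79	HexNAc(5)Hex(5)NeuAc(1)
80	HexNAc(5)Hex(5)NeuAc(2)
81	HexNAc(5)Hex(6)NeuAc(1)
82	HexNAc(5)Hex(6)NeuAc(2)
83	HexNAc(3)Hex(4)Fuc(1)NeuAc(1)
84	HexNAc(3)Hex(4)Fuc(1)NeuAc(2)
85	HexNAc(3)Hex(5)Fuc(1)NeuAc(1)
86	HexNAc(3)Hex(5)Fuc(1)NeuAc(2)
87	HexNAc(3)Hex(6)Fuc(1)NeuAc(1)
88	HexNAc(3)Hex(6)Fuc(1)NeuAc(2)
89	HexNAc(4)Hex(4)Fuc(1)NeuAc(1)
90	HexNAc(4)Hex(4)Fuc(1)NeuAc(2)
91	HexNAc(4)Hex(5)Fuc(1)NeuAc(1)
92	HexNAc(4)Hex(5)Fuc(1)NeuAc(2)
93	HexNAc(4)Hex(6)Fuc(1)NeuAc(1)
94	HexNAc(4)Hex(6)Fuc(1)NeuAc(2)
95	HexNAc(5)Hex(4)Fuc(1)NeuAc(1)
96	HexNAc(5)Hex(4)Fuc(1)NeuAc(2)
97	HexNAc(5)Hex(5)Fuc(1)NeuAc(1)
98	HexNAc(5)Hex(5)Fuc(1)NeuAc(2)
99	HexNAc(5)Hex(6)Fuc(1)NeuAc(1)
100	HexNAc(5)Hex(6)Fuc(1)NeuAc(2)
101	HexNAc(3)Hex(4)Fuc(2)
102	HexNAc(3)Hex(5)Fuc(2)
103	HexNAc(3)Hex(6)Fuc(2)
104	HexNAc(4)Hex(4)Fuc(2)
105	HexNAc(4)Hex(5)Fuc(2)
106	HexNAc(4)Hex(6)Fuc(2)
107	HexNAc(5)Hex(4)Fuc(2)
108	HexNAc(5)Hex(5)Fuc(2)
109	HexNAc(5)Hex(6)Fuc(2)
110	HexNAc(4)Hex(5)NeuAc(3)
111	HexNAc(5)Hex(6)NeuAc(3)
112	HexNAc(6)Hex(7)NeuAc(3)
113	HexNAc(4)Hex(5)Fuc(1)NeuAc(3)
114	HexNAc(5)Hex(6)Fuc(1)NeuAc(3)
115	HexNAc(6)Hex(7)Fuc(1)NeuAc(3)
116	HexNAc(3)Hex(3)Fuc(2)
117	HexNAc(2)Hex(4)Fuc(1)NeuAc(1)
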