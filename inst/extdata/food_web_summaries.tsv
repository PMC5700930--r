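name	N	B	L	q	T	type	id
Akatore Stream	84	43	227	0.16	0.40	River	5
Benguela Current	29	2	196	0.69	0.65	Marine	39
Berwick Stream	77	35	240	0.18	0.40	River	7
Blackrock Stream	86	49	375	0.19	0.42	River	9
Bridge Broom Lake	25	8	104	0.53	0.64	Lake	28
Broad Stream	94	53	564	0.14	0.37	River	1
Canton Creek	102	54	696	0.15	0.38	River	4
Caribbean (2005)	249	5	3302	0.73	0.69	Marine	41
Caribbean Reef	50	3	535	0.94	0.82	Marine	43
Carpinteria Salt Marsh Reserve	126	50	541	0.65	0.85	Marine	36
Caitlins Stream	48	14	110	0.20	0.41	River	12
Chesapeake Bay	31	5	67	0.45	0.62	Marine	26
Coachella Valley	29	3	243	1.21	1.02	Terrestrial	45
Coweeta (1)	58	28	126	0.30	0.52	River	20
Crystal Lake (Delta)	19	3	30	0.17	0.43	Lake	6
Cypress (Wet Season)	64	12	439	0.63	0.66	Terrestrial	34
Dempsters Stream (Autumn)	83	46	414	0.21	0.43	River	13
El Verde Rainforest	155	28	1507	1.01	0.99	Terrestrial	44
Everglades Graminoid Marshes	64	4	681	1.35	1.10	Terrestrial	46
Florida Bay	121	14	1767	0.59	0.59	Marine	29
German Stream	84	48	352	0.20	0.43	River	11
Grassland (U.K.)	61	8	97	0.40	0.69	River	24
Healy Stream	96	47	634	0.22	0.42	River	15
Kyeburn Stream	98	58	629	0.18	0.41	River	8
LilKyeburn Stream	78	42	375	0.23	0.44	River	18
Little Rock Lake	92	12	984	0.67	0.65	Lake	37
Lough Hyne	349	49	5102	0.60	0.60	Lake	31
Mangrove Estuary (Wet Season)	90	6	1151	0.67	0.63	Marine	38
Martins Stream	105	48	343	0.32	0.51	River	21
Maspalomas Pond	18	8	24	0.49	1.01	Lake	27
Michigan Lake	33	5	127	0.37	0.48	Lake	22
Narragansett Bay	31	5	111	0.61	0.68	Marine	33
Narrowdale Stream	71	28	154	0.23	0.44	River	17
N.E. Shelf	79	2	1378	0.73	0.66	Marine	42
North Col Stream	78	25	241	0.28	0.45	River	19
Powder Stream	78	32	268	0.22	0.42	River	14
Scotch Broom	85	1	219	0.40	0.54	Terrestrial	23
Skipwith Pond	25	1	189	0.61	0.54	Lake	32
St. Marks Estuary	48	6	218	0.63	0.67	Marine	35
St. Martin Island	42	6	205	0.59	0.63	Terrestrial	30
Stony Stream	109	61	827	0.15	0.38	River	3
Sutton Stream (Autumn)	80	49	335	0.15	0.40	River	2
Troy Stream	77	40	181	0.19	0.42	River	10
Venlaw Stream	66	30	187	0.23	0.44	River	16
Weddell Sea	483	61	15317	0.72	0.68	Marine	40
Ythan Estuary	82	5	391	0.42	0.50	Marine	25
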