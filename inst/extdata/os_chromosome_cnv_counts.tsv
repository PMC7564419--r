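chromosome	total_genes	significant_genes	cnv_gain_count	cnv_loss_count
1	2652	220	58	205
2	1728	56	16	56
3	1477	60	18	60
4	1011	88	47	82
5	1216	26	9	26
6	1374	21	15	21
7	1269	10	6	10
8	962	261	188	160
9	1063	132	41	132
10	1061	367	8	367
11	1609	428	129	428
12	1326	127	116	127
13	601	6	2	6
14	876	12	11	2
15	931	193	81	191
16	1086	280	7	278
17	1498	207	70	205
18	407	12	2	12
19	1725	108	77	108
20	749	10	6	10
21	341	1	1	1
22	587	37	35	37
X	1118	8	7	8
Y	106	0	0	0
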