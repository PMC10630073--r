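cell_line	n_is	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17
A	1	25	5	1	0.5	0.1	0.05	5	5	5	100	0	0	0	40	3	8	25
B	3	25	5	1	0.5	0.1	0.05	25	50	75	0	100	0	0	3	40	25	8
C	6	25	5	1	0.5	0.1	0.05	5	5	5	0	0	100	0	8	25	40	3
D	10	25	5	1	0.5	0.1	0.05	5	5	5	0	0	0	100	40	25	3	8
JY	NA	0	80	96	98	99.6	99.8	60	35	10	0	0	0	0	9	7	24	56
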