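cell_line	n_is	L	M	N	O	P	Q	R	S	T
CEM1	1	70	60	50	25	12.5	7.5	0.75	0.08	0
CEM6	6	30	30	30	30	30	30	30	30	30
JY	NA	0	10	20	45	57.5	62.5	69.25	69.92	70
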