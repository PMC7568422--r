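gene	OV90	OVCAR4	OVCAR3	OVCAR5	OVCA432
AMH	3.72	4.73	11.70	15.95	30.91
CXCL11	0.65	1.06	0.75	3.36	9.22
EPGN	0.00	0.00	0.21	2.97	34.75
FAM3C	3410.94	5751.98	4598.91	7852.69	10933.33
GDNF	0.00	0.00	0.16	0.00	47.86
LIF	87.28	586.30	616.71	1515.45	1895.35
TGFA	7.34	586.50	870.77	1035.11	5681.16
TNFAIP2	2222.38	3571.95	3406.09	5590.16	8712.42
TNFSF12	2.60	0.56	20.68	27.71	104.14
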