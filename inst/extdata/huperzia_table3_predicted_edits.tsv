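gene	reference	c_to_u	u_to_c	total
atp1	Marchantia	3	0	3
atp4	Marchantia	7	1	8
atp6	Marchantia	9	0	9
atp8	Marchantia	5	2	7
atp9	Marchantia	7	0	7
cob	Marchantia	8	3	11
cox1	Marchantia	19	0	19
cox2	Marchantia	4	0	4
cox3	Marchantia	6	0	6
nad1	Marchantia	16	4	20
nad2	Marchantia	16	0	16
nad3	Marchantia	12	0	12
nad4	Marchantia	21	2	23
nad4L	Marchantia	3	0	3
nad5	Marchantia	15	7	22
nad6	Marchantia	10	1	11
nad9	Marchantia	4	1	5
rpl2	Marchantia	15	24	39
rpl5	Marchantia	6	0	6
rpl6	Marchantia	4	0	4
rpl10	Marchantia	4	14	18
rpl16	Marchantia	2	0	2
rps2	Marchantia	3	1	4
rps3	Marchantia	5	7	12
rps4	Marchantia	5	2	7
rps10	Marchantia	1	2	3
rps11	Marchantia	4	2	6
rps12	Marchantia	1	0	1
rps13	Marchantia	8	0	8
rps14	Marchantia	0	0	0
rps19	Marchantia	1	1	2
sdh3	Marchantia	6	3	9
sdh4	Marchantia	7	2	9
tatC	Marchantia	13	5	18
atp1	Isoetes	8	26	34
atp4	Isoetes	6	5	11
atp6	Isoetes	14	19	33
atp8	Isoetes	4	6	10
atp9	Isoetes	8	0	8
cob	Isoetes	10	6	16
cox1	Isoetes	30	38	68
cox2	Isoetes	2	12	14
cox3	Isoetes	13	19	32
nad1	Isoetes	19	5	24
nad2	Isoetes	23	29	52
nad3	Isoetes	10	4	14
nad4	Isoetes	23	3	26
nad4L	Isoetes	3	2	5
nad5	Isoetes	41	42	83
nad6	Isoetes	13	7	20
nad9	Isoetes	8	14	22
rpl5	Isoetes	4	8	12
rps2	Isoetes	5	9	14
rps3	Isoetes	16	12	28
rps4	Isoetes	5	4	9
sdh3	Isoetes	2	2	4
tatC	Isoetes	12	25	37
atp1	Selaginella	6	5	11
atp8	Selaginella	4	7	11
cox2	Selaginella	12	12	24
cox3	Selaginella	13	12	25
nad1	Selaginella	14	15	39
nad2	Selaginella	18	26	44
nad3	Selaginella	7	5	12
nad4	Selaginella	17	25	42
nad4L	Selaginella	4	5	9
nad5	Selaginella	26	40	66
nad6	Selaginella	5	14	19
nad9	Selaginella	6	10	16
tatC	Selaginella	14	32	46
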