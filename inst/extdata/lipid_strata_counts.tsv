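hdl_stratum	ldl_stratum	hiv_negative_n	hiv_positive_n
<=40	<=100	17	46
<=40	100-130	12	27
<=40	130-160	19	7
<=40	>=160	3	4
<=40	not_measured	17	23
40-60	<=100	15	19
40-60	100-130	1	11
40-60	130-160	7	12
40-60	>=160	13	4
40-60	not_measured	1	1
>=60	<=100	8	15
>=60	100-130	8	7
>=60	130-160	2	6
>=60	>=160	3	6
>=60	not_measured	1	4
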