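section	category	n	denominator
gender	female	5715	10114
gender	male	3459	10114
gender	unknown	940	10114
age_group	<18	819	10114
age_group	18-44	866	10114
age_group	45-64	2382	10114
age_group	65-74	1232	10114
age_group	>=75	524	10114
age_group	unknown	4291	10114
reporter	consumer	4081	10114
reporter	pharmacist	260	10114
reporter	physician	1600	10114
reporter	other health professional	4015	10114
reporter	unknown	185	10114
country	United States	7350	10114
country	Canada	222	10114
country	Japan	256	10114
country	Germany	720	10114
country	France	666	10114
country	Other	900	10114
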