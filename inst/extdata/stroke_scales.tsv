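abbreviation	name	doc_freq	tfidf
FMA	Fugl-meyer assessment	248	8.967532517
Ashworth	Ashworth scale	138	14.86100317
BI	Barthel index	115	21.46757397
ARAT	Action research arm test	81	12.07425711
WMFT	Wolf motor function test	75	13.60741523
RS	Rankin scale	55	19.33877467
FIM	Functional independence measure	42	15.96626141
MOM	Main outcome measure	41	5.37136245
MI	Motricity index	40	7.990027148
SIAS	Stroke impact scale	25	11.18520612
BBS	Berg balance scale	23	24.26706778
MAS	Motor assessment scale	22	14.7664421
RMA	Rivermead motor assessment	20	17.80426457
AAI	Arm index	14	12.81320984
BBT	Box and block test	14	9.018969872
FAT	Frenchay arm test	13	18.36081387
NIHSS	Nihss score	12	15.94629694
POM	Primary outcome measure	11	5.529408988
JTTHF	Jebsen-Taylor Test of Hand Function	8	15.01043442
DAS	Disability assessment scale	8	14.62921899
BRUNSTROM	Brunnstrom scale	7	9.218846945
COPM	Canadian occupational performance measure	7	13.53841027
NHPT	Nine hole peg test	7	16.42409311
VAS	Visual analog scale	7	7.112188973
RS	Rankin scale	7	19.33877467
AMAT	Arm motor ability test	6	10.48555474
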