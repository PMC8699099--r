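	K1	K15	K8	K12	K16	K6	K11	K21	K4	K20	B10	K18	K19	KCN	K7	K14	K10	K13	TNF	K2	K5	K17	K3	SHK	K9
K1	23.3	19.6	10.1	9.6	9.8	8.1	5.9	2.7	2.2	-	-	2.9	-	9.5	2.3	2.5	-	-	-	4.1	3.9	3.7	-	-	-
K15		23.3	10.4	9.9	10.1	7.9	5.1	2.1	2.0	-	-	2.7	-	9.8	2.6	3.6	-	-	-	4.9	4.8	5.0	-	-	-
K8			22.8	19.5	20.4	7.8	5.8	-	2.0	-	-	-	-	8.1	2.3	-	-	-	-	2.7	2.8	2.8	-	-	-
K12				22.8	19.2	7.6	5.7	-	-	-	-	-	-	8.9	-	-	-	-	-	2.5	2.5	2.6	-	-	-
K16					22.7	7.5	5.0	-	2.1	-	-	2.2	-	8.0	-	2.3	-	-	-	3.2	3.0	3.3	-	-	-
K6						24.4	7.8	5.8	3.3	-	-	3.1	2.2	11.6	2.2	2.3	-	-	-	3.7	3.8	3.5	-	-	-
K11							26.9	14.2	5.3	-	-	-	-	8.7	-	-	-	-	-	-	-	-	-	-	-
K21								25.2	2.1	-	-	-	-	9.2	-	-	-	-	-	-	-	-	-	2.7	-
K4									27.3	-	-	-	2.3	3.3	-	-	-	-	-	-	-	-	-	-	-
K20										25.3	22.9	-	-	-	5.6	6.6	-	-	-	-	-	-	-	-	-
B10											25.0	-	2.2	2.1	5.7	6.6	-	-	-	-	-	-	-	-	-
K18												21.8	-	2.5	-	-	-	-	-	-	-	-	-	-	-
K19													54.7	-	-	2.0	-	-	-	-	-	-	-	-	-
KCN														27.0	3.8	3.4	-	-	-	4.8	4.5	4.8	-	-	-
K7															24.9	13.4	-	-	-	3.0	3.0	-	-	-	-
K14																27.1	2.4	2.2	2.4	3.0	3.0	3.0	-	-	-
K10																	25.6	21.4	23.5	-	-	-	-	-	-
K13																		27.0	22.4	-	-	-	-	-	-
TNF																			26.7	-	-	-	-	-	-
K2																				12.1	10.7	10.8	-	-	-
K5																					12.0	10.2	-	-	-
K17																						11.9	-	-	-
K3																							62.7	50.3	-
SHK																								63.6	-
K9																									39.6
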