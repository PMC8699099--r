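protein	short_label	accession	btb_start	btb_end	ctd_start	ctd_end	disorder_regions	note
KCTD1	K1	Q719H9	30	133	139	239	1-17;242-257
KCTD2	K2	Q14681	72	178	183	239	1-71;239-263
KCTD3	K3	Q9Y597	18	115	NA	NA	1-17;139-181;598-815	C-terminal beta-propeller; no canonical CTD identified
KCTD4	K4	Q8WVF5	33	135	140	259	1-32;198-217
KCTD5	K5	Q9NXV2	42	149	154	211	1-41;211-234
KCTD6	K6	Q8NC69	12	107	114	234
KCTD7	K7	Q96MP8	50	158	162	289	1-46;196-224
KCTD8	K8	Q6ZWB6	44	145	205	322	1-41;148-203;325-434
KCTD9	K9	Q7L273	89	191	NA	NA	73-88	C-terminal beta-solenoid; no canonical CTD identified
KCTD10	K10	Q9H3F6	33	129	141	260	1-18;274-295
KCTD11	K11	Q693B1	14	123	126	271		numbering of the long variant
KCTD12	K12	Q96CX2	34	131	206	325	1-29;132-204
KCTD13	K13	Q8WZ19	41	142	150	271	1-40;272-303;311-329
KCTD14	K14	Q9BQ13	33	124	125	255	1-28
KCTD15	K15	Q96SI1	56	162	165	265	1-43;266-283
KCTD16	K16	Q68DU8	25	122	162	280	1-21;124-161;281-389
KCTD17	K17	Q8N5Z5	30	135	139	196	1-29;197-260;265-321
KCTD18	K18	Q6PI47	12	118	140	242	242-426
KCTD19	K19	Q17RG1	13	107	396	487	108-171;259-282;501-756;788-803	multi-BTB chain; CTD range is the third BTB domain (the region aligned in the family comparison) -- explicit overridable choice
KCTD20	K20	Q7Z5Y7	117	216	218	356	1-115;359-419
KCTD21	K21	Q4G0X4	4	107	109	260		CTD length 152 exceeds the published 57-146 summary range; kept as printed (known inconsistency)
KCNRG	KCN	Q8N5I3	5	104	107	245	246-272
SHKBP1	SHK	Q8TBC3	19	118	NA	NA	139-192;604-707	C-terminal beta-propeller; no canonical CTD identified
TNFAIP1	TNF	Q13829	28	130	137	257	1-27;258-290;299-316
BTBD10	B10	Q9BSF8	149	266	268	405	1-148;409-475
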