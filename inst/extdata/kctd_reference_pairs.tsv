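protein	domain	pdb_code	resolution	published_rmsd	published_n_superimposed
KCTD1	BTB	5BXD	1.8	0.6	103
KCTD1	BTB	5BXB	2.2	0.4	103
KCTD1	Full-length	6S4L	2.4	0.8	205
KCTD5	BTB	3DRZ	1.9	0.8	102
KCTD5	Full-length	3DRX	3.1	2.1	163
KCTD5	Full-length	3DRY	3.3	2.4	133
KCTD8	CTD	6G57	2.8	1.8	88
KCTD9	BTB	5BXH	2.8	0.7	97
KCTD10	BTB	5FTA	2.6	0.4	96
KCTD12	CTD	6QZL	2.0	0.7	100
KCTD12	CTD-Gb1g2	6M8S	3.7	0.8	103
KCTD13	BTB	4UIJ	2.7	0.3	102
KCTD16	BTB	5A15	2.8	0.5	91
KCTD16	BTB	6OCR	2.3	0.4	90
KCTD16	BTB	6I0Q	2.3	0.7	95
KCTD16	BTB	6OCT	NA	0.5	91
KCTD16	CTD	6QB7	2.2	0.7	110
KCTD16	BTB-GABAB2	6OCP	2.3	0.5	91
KCTD16	BTB-GABAB2	6M8R	3.2	0.5	93
KCTD17	BTB	5A6R	2.8	0.7	101
SHKBP1	BTB	4CRH	1.7	1.0	90
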