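label	x	y	z
Fp1	-27.626	85.024	29.048
Fp2	27.626	85.024	29.048
F7	-72.326	52.548	29.048
F3	-40.705	60.669	59.147
Fz	0	55.252	76.048
F4	40.705	60.669	59.147
F8	72.326	52.548	29.048
FC5	-71.108	32.223	52.358
FC1	-26.691	32.966	83.886
FC2	26.691	32.966	83.886
FC6	71.108	32.223	52.358
T7	-89.399	0	29.048
C3	-55.252	0	76.048
Cz	0	0	94
C4	55.252	0	76.048
T8	89.399	0	29.048
TP9	-81.023	-26.326	-39.726
CP5	-71.108	-32.223	52.358
CP1	-26.691	-32.966	83.886
CP2	26.691	-32.966	83.886
CP6	71.108	-32.223	52.358
TP10	81.023	-26.326	-39.726
P7	-72.326	-52.548	29.048
P3	-40.705	-60.669	59.147
Pz	0	-55.252	76.048
P4	40.705	-60.669	59.147
P8	72.326	-52.548	29.048
PO9	-55.252	-76.048	0
O1	-27.626	-85.024	29.048
Oz	0	-89.399	29.048
O2	27.626	-85.024	29.048
PO10	55.252	-76.048	0
AF7	-52.548	72.326	29.048
AF3	-27.663	78.11	44.379
AF4	27.663	78.11	44.379
AF8	52.548	72.326	29.048
F5	-58.161	58.257	45.381
F1	-20.945	59.648	69.566
F2	20.945	59.648	69.566
F6	58.161	58.257	45.381
FT9	-89.399	29.048	0
FT7	-85.024	27.626	29.048
FC3	-51.091	34.055	71.175
FC4	51.091	34.055	71.175
FT8	85.024	27.626	29.048
FT10	89.399	29.048	0
C5	-76.048	0	55.252
C1	-29.048	0	89.399
C2	29.048	0	89.399
C6	76.048	0	55.252
TP7	-85.024	-27.626	29.048
CP3	-51.091	-34.055	71.175
CPz	0	-29.048	89.399
CP4	51.091	-34.055	71.175
TP8	85.024	-27.626	29.048
P5	-58.161	-58.257	45.381
P1	-20.945	-59.648	69.566
P2	20.945	-59.648	69.566
P6	58.161	-58.257	45.381
PO7	-52.548	-72.326	29.048
PO3	-27.663	-78.11	44.379
POz	0	-76.048	55.252
PO4	27.663	-78.11	44.379
PO8	52.548	-72.326	29.048
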