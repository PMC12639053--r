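Run	Protein.Group	Stripped.Sequence	Precursor.Id	Precursor.Quantity	Q.Value	Lib.Q.Value	PG.Q.Value	Lib.PG.Q.Value
R1	P1_HUMAN;P9_HUMAN	PEPTIDEA	PEPTIDEA2.1	5	0.001	0.002	0.01	0.001
R1	P1_HUMAN;P9_HUMAN	PEPTIDEA	PEPTIDEA2.2	4	0.002	0.002	0.01	0.001
R1	P1_HUMAN;P9_HUMAN	PEPTIDEA	PEPTIDEA3.1	3	0.003	0.002	0.01	0.001
R1	P1_HUMAN;P9_HUMAN	PEPTIDEA	PEPTIDEA3.2	2	0.004	0.002	0.01	0.001
R2	P1_HUMAN;P9_HUMAN	PEPTIDEA	PEPTIDEA2.1	6	0.001	0.002	0.01	0.001
R1	P2_YEAST	GLNVVEAK	GLNVVEAK2.1	10	0.02	0.002	0.01	0.001
R1	P2_YEAST	GLNVVEAK	GLNVVEAK2.2	9	0.001	0.02	0.01	0.001
R2	P2_YEAST	GLNVVEAK	GLNVVEAK2.1	8	0.001	0.002	0.06	0.001
R2	P2_YEAST	GLNVVEAK	GLNVVEAK2.2	7	0.001	0.002	0.01	0.02
R1	P3_ECOLI	AVFPSIVGR	AVFPSIVGR2.1	11	0.005	0.005	0.02	0.005
R2	P3_ECOLI	AVFPSIVGR	AVFPSIVGR2.1	12	0.005	0.005	0.02	0.005
R3	P2_YEAST	GLNVVEAK	GLNVVEAK2.1	13	0.001	0.002	0.01	0.001
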