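R.FileName	PG.ProteinAccessions	PEP.StrippedSequence	PEP.Quantity	EG.Qvalue	PG.Qvalue
R1	Q2_YEAST;Q1_YEAST	AAAK	100	0.001	0.01
R1	Q3_ECOLI	CCCK	50	0.001	0.01
R2	Q1_YEAST;Q2_YEAST	AAAK	110	0.001	0.01
R2	Q3_ECOLI	CCCK	55	0.001	0.01
R3	Q3_ECOLI	CCCK	60	0.001	0.01
R3	Q4_HUMAN	DDDK	70	0.03	0.01
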