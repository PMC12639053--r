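Accession	Top	Protein Group	Area S1	Area S2
A1_HUMAN	TRUE	1	10	12
A2_HUMAN	FALSE	1	8	9
B1_YEAST	TRUE	2	5	NA
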