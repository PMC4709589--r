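Variant	SNAP	Pmut	SNPS3D	I-Mutant3.0	PolyPhen	Eris	FoldX	NeEMO	Conservation	StructuralEffect
V138A	Neutral	Neutral	Tolerated 1.10	Increase 5	Benign 0.012	NA	NA	NA	Variable	NA
P165S	Neutral	Neutral	Tolerated 1.23	Increase 8	Benign 0.002	NA	NA	NA	Variable	NA
Q157H	Neutral	Neutral	Tolerated 1.44	Increase 6	Benign 0.289	NA	NA	NA	Variable	NA
K423E	Neutral	Neutral	Deleterious -2.72	Decrease 7	Probably damaging 0.999	NA	NA	NA	Conserved	NA
P200Q	Neutral	Pathological	Deleterious -0.42	Decrease 8	Possibly damaging 0.952	-4.46	-2.60	-0.02	Conserved	Disturbs the Cys201-Cys208 interaction
N203K	Neutral	Pathological	Tolerated 0.44	Decrease 2	Benign 0.032	3.61	1.06	0.65	Conserved	Disturbs a putative linear motif
D254H	Non-Neutral	Pathological	Deleterious -3.68	Decrease 8	Possibly damaging 0.885	4.09	3.75	1.48	Conserved	Reduces beta2-beta3-loop stability
K291I	Neutral	Pathological	Tolerated 0.62	Decrease 6	Possibly damaging 0.736	-1.53	-0.69	-0.48	Variable	Reduces protein stability
P317R	Non-Neutral	Pathological	Deleterious -2.28	Decrease 8	Probably damaging 0.999	-3.17	1.66	0.45	Conserved	Reduces catalytic site stability
R371H	Non-Neutral	Pathological	Deleterious -2.14	Decrease 9	Probably damaging 0.997	-5.66	2.45	2.23	Conserved	Reduces protein stability
H374R	Non-Neutral	Pathological	Deleterious -3.02	Decrease 6	Probably damaging 0.999	3.25	3.05	-0.70	Conserved	Impairs iron ion coordination
R398X	NA	NA	NA	NA	NA	NA	NA	NA	NA	Inserts a STOP codon
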