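# PHD2 (EGLN1) variants reported in polycythemic patients
V138A
Q157H
P165S
P200Q
N203K
D254H
K291I
P317R
R371H
H374R
R398X   # nonsense: truncates the C-terminal tail
K423E
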