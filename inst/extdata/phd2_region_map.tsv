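# PHD2 domain organization (closed 1-based intervals)
n_terminal_disordered	1-187
oxygenase_domain	188-418
c_terminal_tail	419-426
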