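# PHD2 functional-site position sets (1-based residue numbers)
# set_name	positions (comma-separated; a-b ranges allowed)
iron_triad	313,315,374
og_contacts	254
disulfide_pair	201,208
beta2_beta3_loop	236-254
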