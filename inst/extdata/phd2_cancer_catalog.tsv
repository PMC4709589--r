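# COSMIC-derived PHD2 positions mutated in human cancers, with the variant
# of the polycythemia panel each was reported next to.
variant	position	primary_site	histology	subtype	source_id
N203K	202	Urinary tract	Bladder	N.S.	21822268
K291I	292	Large intestine	Colon	Adenocarcinoma	22895193
H374R	344	Lung	N.S.	Small cell carcinoma	22941189
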