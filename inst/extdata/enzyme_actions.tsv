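symbol	enzyme_class	motif	action
Man1a2	GH	high-mannose-branched	removes
Man2a2	GH	high-mannose-branched	removes
St6gal2	GT	sialyl-Gal-GalNAc	adds
B4galnt1	GT	terminal-GalNAc	adds
Fut9	GT	Lewis-x	adds
St8sia3	GT	poly-Sia	adds
St8sia5	GT	poly-Sia	adds
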