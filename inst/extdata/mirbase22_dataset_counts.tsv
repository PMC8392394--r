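set	species	count
training	Arabidopsis thaliana	326
training	Glycine max	684
training	Oryza sativa	604
training	Physcomitrella patens	247
training	Medicago truncatula	672
training	Sorghum bicolor	205
training	Arabidopsis lyrata	205
training	Zea mays	168
training	Solanum lycopersicum	112
testing	Remaining plant species	5323
negative_training	CDS-derived pseudo hairpins	5186
negative_testing	CDS-derived pseudo hairpins	3466
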