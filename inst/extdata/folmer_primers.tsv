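name	forward	reverse
LCO1490/HCO2198	GGTCAACAAATCATAAAGATATTGG	TAAACTTCAGGGTGACCAAAAAATCA
dgLCO1490/dgHCO2198	GGTCWACWAAYCATAAAGATATTGG	TAAACYTCWGGRTGWCCRAARAAYCA
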