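# name	sequence	orientation
8F	AGAGTTTGAT(C/T)(A/C)TGGCTCAG	forward
Arch21F	TTCCGGTTGATCCTGCCGGA	forward
1492R	GGTTACCTTGTTA(C/T)GACTT	reverse
26ABF	GSVYACTGCTATCGGMTT	forward
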