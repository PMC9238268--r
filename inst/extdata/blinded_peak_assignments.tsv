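center	unknown1	unknown2	unknown3	unknown1_overlap	unknown2_overlap	unknown3_overlap
569	control	control	EGF	.	.	FGF2
621	FGF2	control	FGF2	EGF	.	.
676	control	control	EGF	.	.	FGF2
1124	FGF2	control	EGF	.	.	FGF2
1248	FGF2	EGF	FGF2	.	control	EGF
1335	FGF2	control	EGF	.	EGF	.
1446	FGF2	control	EGF	.	EGF	.
1654	FGF2	control	control	.	.	.
1926	FGF2	EGF	control	.	.	EGF
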