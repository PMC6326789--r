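chr1	3959	3960	AluYh3	262	-	0.12
chr1	23208	23209	AluY	257	-	0.09
chr1	15000	15001	AluYa5	281	+	0.285
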