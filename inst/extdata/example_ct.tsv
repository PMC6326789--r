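sample_id	primer_pair	ct
s1	reference	20.10
s1	reference	20.05
s1	reference	20.15
s1	include_isoform	25.02
s1	include_isoform	24.98
s1	include_isoform	25.00
s1	skip_isoform	24.01
s1	skip_isoform	23.95
s1	skip_isoform	24.04
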