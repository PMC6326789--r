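sample_id	isoform_id	fragment_length	intensity	contains_target_exon
with_alu	include	394	215.91	TRUE
with_alu	skip	251	113.45	FALSE
no_alu	include	394	315.20	TRUE
no_alu	skip	251	50.20	FALSE
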