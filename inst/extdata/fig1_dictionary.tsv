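term	entity_id	entity_type	source
OxyR	TF-OXYR	TF	example
katG	GENE-KATG	GENE	example
ahpCF	GENE-AHPCF	GENE	example
oxyS	GENE-OXYS	GENE	example
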