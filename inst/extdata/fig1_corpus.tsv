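doc_id	text
fig1	Activated OxyR then induces transcription of antioxidant genes, including katG, ahpCF, and oxyS
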