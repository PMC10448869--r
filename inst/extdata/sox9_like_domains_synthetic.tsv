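gene	protein_length	domain_name	start	end
SOX9	509	DIM	66	102
SOX9	509	HMG	106	182
SOX9	509	K2	299	336
SOX9	509	PQA	339	379
SOX9	509	TA	402	496
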