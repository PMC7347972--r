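class	mutations	indels	total_length
CDS	1554	83	60206
IGS	1927	410	36968
intron	490	104	13781
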