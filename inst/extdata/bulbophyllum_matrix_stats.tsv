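matrix	pis	sites
whole_plastome	2429	163916
top10_markers	285	7087
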