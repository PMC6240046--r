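roi	p
parahippocampal_gyrus_left	0.038
parahippocampal_gyrus_right	0.013
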