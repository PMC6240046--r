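roi	p
anterior_cingulate_medial_prefrontal	0.003
hippocampus_left	0.006
hippocampus_right	0.031
parahippocampal_gyrus_left	0.010
thalamus_left	0.013
thalamus_right	0.016
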