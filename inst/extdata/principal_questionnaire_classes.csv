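class_label,first,last
School characterization,1,84
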