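class_label,count
probable,55
possible,23
band5_only,13
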