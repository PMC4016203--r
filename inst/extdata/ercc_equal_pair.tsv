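id	concentration
ERCC-00033	7.06e-07
ERCC-00046	7.08e-07
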