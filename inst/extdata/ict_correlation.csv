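indicator,internet,cellular
internet,1.000,0.805
cellular,0.805,1.000
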