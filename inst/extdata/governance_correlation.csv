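indicator,effectiveness,stability,corruption,regulation,law,accountability
effectiveness,1.000,0.639,0.847,0.903,0.904,0.682
stability,0.639,1.000,0.677,0.627,0.754,0.598
corruption,0.847,0.677,1.000,0.823,0.886,0.709
regulation,0.903,0.627,0.823,1.000,0.885,0.727
law,0.904,0.754,0.886,0.885,1.000,0.787
accountability,0.682,0.598,0.709,0.727,0.787,1.000
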