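backbone,ce_map,cace_map
MobileNetv3-large,18.09,32.51
VGG300,40.00,48.99
VGG512,42.79,52.75
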