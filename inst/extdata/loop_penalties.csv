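term,value
hairpin_a,5.4
hairpin_b,0.15
bulge_a,3.8
bulge_b,0.45
internal_a,2.6
internal_b,0.4
multi_close,3.4
multi_branch,0.4
multi_unpaired,0.1
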