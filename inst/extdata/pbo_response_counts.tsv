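population	died	normal_growth	limited_growth
JCWL-R	7	19	74
JCJT-R	5	17	78
JYJD-R	9	9	82
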