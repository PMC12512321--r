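"name","p0","p1"
"Null",0.1,0.1
"As powered",0.1,0.04
"Smaller difference",0.1,0.06
"Larger difference",0.1,0.03
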