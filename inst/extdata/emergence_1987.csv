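percent,observed,predicted
10,261.0,265.0
15,261.5,266.5
25,263.5,268.5
50,267.5,274.5
75,269.5,279.0
90,279.0,282.0
95,284.0,284.0
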