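percent,observed,predicted
10,256.0,267.0
15,260.0,268.0
25,263.5,270.0
50,266.5,273.5
75,269.5,278.5
90,275.0,282.0
95,279.0,284.0
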