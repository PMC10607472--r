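stage,threshold
egg,3.1
larva,3.8
larva,4.3
pupa,4.0
pupa,4.4
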