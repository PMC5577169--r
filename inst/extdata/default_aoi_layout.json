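{"L1":{"rect":[280,320,680,538]},"L2":{"rect":[280,542,680,760]},"R1":{"rect":[1240,320,1640,538]},"R2":{"rect":[1240,542,1640,760]}}
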