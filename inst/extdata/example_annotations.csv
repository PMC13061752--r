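 ,X,Y,Slice
1,101.5,88.25,1
2,118.0,132.5,1
3,97.75,180.0,1
4,121.25,226.5,1
5,99.0,274.25,1
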