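(Zv9:0.42,(hipCom0:0.23,((fr3:0.11,gasAcu1:0.09):0.05,(oryLat2:0.10,oreNil2:0.08):0.05):0.06):0.02);
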