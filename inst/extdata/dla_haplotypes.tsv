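drb1	dqa1	dqb1
002:01	009:01	001:01
006:01	050:11	007:01
015:01	009:01	001:01
023:01	003:01	005:01
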