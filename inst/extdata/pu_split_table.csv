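class,train,val,test,total
Asphalt,66,65,6500,6631
Meadows,186,184,18279,18649
Gravel,20,20,2059,2099
Trees,30,30,3004,3064
Painted metal sheets,13,13,1319,1345
Bare soil,50,49,4930,5029
Bitumen,13,13,1304,1330
Self-blocking bricks,36,36,3610,3682
Shadows,9,9,929,947
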