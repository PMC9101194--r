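item_id,n,mean,sd
cardio,10,590.6,1.838
situps,10,37.8,0.789
jump,10,192,1.160
flex,10,18.59,0.099
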