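item_id,n,pf_star
cardio,10,4.03
situps,10,6.09
jump,10,6.04
flex,10,5.93
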