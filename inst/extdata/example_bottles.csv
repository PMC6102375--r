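subject_id,day_index,bottle_contents,consumed_g
m01,1,water,2.0
m01,1,water,1.9
m01,2,water,2.1
m01,2,water,1.8
m01,3,water,0.9
m01,3,sucrose,11.2
m01,4,sucrose,11.9
m01,4,water,0.7
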