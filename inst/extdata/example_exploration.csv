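subject_id,session,novel_time_s,familiar_time_s
m01,training,12.4,11.9
m01,testing,9.1,5.8
m02,training,8.2,8.4
m02,testing,1.6,1.2
m03,training,14.0,8.9
m03,testing,10.3,9.8
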