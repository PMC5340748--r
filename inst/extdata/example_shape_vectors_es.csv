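subject_id,group,mode_1,mode_2,mode_3,mode_4
Control_1,control,-190,175,-220,-170
Control_2,control,-299,533,-104,146
Control_3,control,-834,90,184,-262
Control_4,control,-212,-145,-214,-237
AS_1,AS,1012,434,117,208
AS_2,AS,-328,-292,693,355
AS_3,AS,792,-406,153,-413
AS_4,AS,-45,-512,-494,450
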