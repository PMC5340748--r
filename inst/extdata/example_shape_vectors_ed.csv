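subject_id,group,mode_1,mode_2,mode_3,mode_4
Control_1,control,-140,316,121,-20
Control_2,control,-98,282,204,319
Control_3,control,-574,91,121,-46
Control_4,control,-116,-224,34,-227
AS_1,AS,816,117,-359,209
AS_2,AS,-607,-356,-518,120
AS_3,AS,390,81,-111,-432
AS_4,AS,380,-652,346,114
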