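true_day,pred_1,pred_3,pred_7,pred_9,pred_11
1,378,0,0,0,0
3,0,368,0,0,0
7,0,0,343,9,0
9,0,0,65,249,9
11,0,0,2,10,308
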