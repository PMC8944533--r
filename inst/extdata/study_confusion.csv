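truth,pred_0,pred_1,pred_ge2
0,697,21,0
1,4,274,2
>=2,0,8,24
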