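farm,month,ls0,ls1,ls2,ls3
farm1,1,220,82,8,0
farm1,2,226,95,5,0
farm1,3,228,101,8,1
farm1,4,240,85,10,1
farm1,5,254,86,10,0
farm1,6,246,81,12,2
farm1,7,260,63,9,0
farm1,8,261,66,9,0
farm1,9,197,122,15,3
farm2,1,73,31,4,0
farm2,2,70,43,5,0
farm2,3,67,50,3,1
farm2,4,89,32,5,0
farm2,5,93,24,5,0
farm2,6,87,36,5,1
farm2,7,80,39,4,1
farm2,8,89,42,3,0
farm2,9,93,41,3,0
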