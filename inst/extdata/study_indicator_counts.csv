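farm,month,sw0,sw1,awd0,awd1,shh0,shh1,oh0,oh1,total0,total1,total2,total3
farm1,1,284,26,280,30,294,16,274,36,222,72,14,2
farm1,2,297,29,286,40,312,14,287,39,215,102,7,2
farm1,3,311,27,312,26,308,30,297,41,230,92,16,0
farm1,4,318,18,314,22,314,22,281,55,235,86,14,1
farm1,5,320,30,324,26,339,11,303,47,251,86,12,1
farm1,6,315,26,315,26,323,18,297,44,243,82,16,0
farm1,7,317,15,315,17,323,9,287,45,256,67,8,1
farm1,8,311,25,313,23,328,8,296,40,251,75,9,1
farm1,9,299,38,290,47,320,17,268,69,191,124,19,3
farm2,1,102,6,100,8,100,8,88,20,70,34,4,0
farm2,2,114,4,106,12,108,10,80,38,61,51,5,1
farm2,3,111,10,111,10,112,9,86,35,64,52,3,2
farm2,4,121,5,121,5,114,12,104,22,88,33,4,1
farm2,5,117,5,116,6,114,8,104,18,91,26,4,1
farm2,6,118,11,117,12,124,5,107,22,87,35,6,1
farm2,7,116,8,108,16,117,7,97,27,76,38,10,0
farm2,8,124,10,122,12,128,6,108,26,88,39,6,1
farm2,9,129,8,123,14,131,6,108,29,88,43,4,2
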