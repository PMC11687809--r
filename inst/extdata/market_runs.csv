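length,nasdaq,djia,nikkei,ipc
1,539,518,502,449
2,253,262,258,232
3,121,116,118,131
4,56,60,66,79
5,36,30,19,40
6,9,13,13,15
7,8,12,7,5
8,4,4,5,3
9,2,2,2,1
10,2,1,1,2
11,2,0,0,0
12,0,1,1,0
13,0,0,1,1
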