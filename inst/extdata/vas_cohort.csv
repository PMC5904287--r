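case,vas_pre,vas_post,relief_printed
1,9.2,8.2,11
2,7.5,6,20
3,5,3,40
4,8,6,25
5,5.6,2,64
6,4.8,4.5,6
7,6.7,5.1,24
8,9,7.5,17
9,10,8,20
10,9,8.5,5.56
11,7,6.2,11.4
12,6.4,6,6.25
13,6.7,3,55.2
14,6.4,2,68.7
15,9.8,3,69.4
16,8.3,8,3.6
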