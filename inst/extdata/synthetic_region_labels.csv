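index,label,brain_region,function
0,Right_SYN00,synthetic region 0,visual processing (synthetic)
1,Right_SYN01,synthetic region 1,attention (synthetic)
2,Right_SYN02,synthetic region 2,auditory (synthetic)
3,Right_SYN03,synthetic region 3,default mode (synthetic)
4,Right_SYN04,synthetic region 4,somatomotor (synthetic)
5,Right_SYN05,synthetic region 5,visual processing (synthetic)
6,Right_SYN06,synthetic region 6,attention (synthetic)
7,Right_SYN07,synthetic region 7,auditory (synthetic)
8,Right_SYN08,synthetic region 8,default mode (synthetic)
9,Right_SYN09,synthetic region 9,somatomotor (synthetic)
10,Right_SYN10,synthetic region 10,visual processing (synthetic)
11,Right_SYN11,synthetic region 11,attention (synthetic)
12,Right_SYN12,synthetic region 12,auditory (synthetic)
13,Right_SYN13,synthetic region 13,default mode (synthetic)
14,Right_SYN14,synthetic region 14,somatomotor (synthetic)
15,Right_SYN15,synthetic region 15,visual processing (synthetic)
16,Right_SYN16,synthetic region 16,attention (synthetic)
17,Right_SYN17,synthetic region 17,auditory (synthetic)
18,Right_SYN18,synthetic region 18,default mode (synthetic)
19,Right_SYN19,synthetic region 19,somatomotor (synthetic)
20,Left_SYN00,synthetic region 20,visual processing (synthetic)
21,Left_SYN01,synthetic region 21,attention (synthetic)
22,Left_SYN02,synthetic region 22,auditory (synthetic)
23,Left_SYN03,synthetic region 23,default mode (synthetic)
24,Left_SYN04,synthetic region 24,somatomotor (synthetic)
25,Left_SYN05,synthetic region 25,visual processing (synthetic)
26,Left_SYN06,synthetic region 26,attention (synthetic)
27,Left_SYN07,synthetic region 27,auditory (synthetic)
28,Left_SYN08,synthetic region 28,default mode (synthetic)
29,Left_SYN09,synthetic region 29,somatomotor (synthetic)
30,Left_SYN10,synthetic region 30,visual processing (synthetic)
31,Left_SYN11,synthetic region 31,attention (synthetic)
32,Left_SYN12,synthetic region 32,auditory (synthetic)
33,Left_SYN13,synthetic region 33,default mode (synthetic)
34,Left_SYN14,synthetic region 34,somatomotor (synthetic)
35,Left_SYN15,synthetic region 35,visual processing (synthetic)
36,Left_SYN16,synthetic region 36,attention (synthetic)
37,Left_SYN17,synthetic region 37,auditory (synthetic)
38,Left_SYN18,synthetic region 38,default mode (synthetic)
39,Left_SYN19,synthetic region 39,somatomotor (synthetic)
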