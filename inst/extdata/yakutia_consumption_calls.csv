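sample_id,drink,tobacco_tier
4,herbal_tea,low
46,coffee_and_theophylline,low
37,nothing,low
10,nothing,low
3,nothing,low
38,nothing,low
13,nothing,low
29,nothing,very_high
45,black_tea,low
36,black_tea,low
26,black_tea,low
27,green_tea,medium
8,green_tea,medium
12,green_tea,high
44,herbal_tea,low
11,black_tea,low
20,herbal_tea,low
17,green_tea,low
40,green_tea,low
21,coffee_and_theophylline,medium
16,coffee,low
30,theophylline_only,high
22,nothing,low
24,nothing,low
43,green_tea,low
1,herbal_tea,low
35,black_tea,low
19,green_tea,low
41,green_tea,very_high
34,black_tea,low
23,herbal_tea,low
28,green_tea,low
47,coffee,low
39,coffee,medium
14,black_tea,high
9,black_tea,medium
15,black_tea,low
42,herbal_tea,low
32,black_tea,low
7,black_tea,medium
25,herbal_tea,low
31,coffee_and_theophylline,low
2,theophylline_only,low
33,black_tea,medium
18,black_tea,low
5,herbal_tea,low
6,black_tea,low
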