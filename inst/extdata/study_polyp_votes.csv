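polyp_id,pathology,majority_answer,majority_pct,conf_1,conf_2,conf_3,conf_4,conf_5,mean_likert_printed
1,benign,benign,53,0,4,16,11,1,3.28
2,cancer,cancer,69,0,2,17,12,1,3.38
3,cancer,benign,72,1,5,17,9,0,3.06
4,benign,cancer,75,0,1,14,14,3,3.59
5,benign,benign,78,1,5,16,8,2,3.16
6,cancer,benign,63,0,6,15,9,2,3.22
7,benign,cancer,91,0,4,12,11,5,3.53
8,cancer,cancer,91,0,1,9,16,6,3.84
9,benign,benign,75,1,8,10,12,1,3.13
10,cancer,benign,63,1,4,14,10,3,3.31
11,benign,benign,73,0,12,12,6,2,2.94
12,benign,cancer,97,0,3,13,12,4,3.53
13,cancer,benign,78,1,9,15,6,1,2.91
14,cancer,even,50,0,7,16,6,3,3.16
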