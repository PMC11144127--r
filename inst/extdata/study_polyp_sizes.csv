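polyp_id,pathology,estimate_mm,estimate_min_mm,estimate_max_mm,actual_mm,fully_visible
1,benign,60,30,150,120,FALSE
2,cancer,20,10,40,29,TRUE
3,benign,44,14,70,46,TRUE
4,benign,37,15,80,30,TRUE
5,benign,20,10,50,18,TRUE
6,cancer,26,8,80,24,TRUE
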