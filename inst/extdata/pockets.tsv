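# Beta-chain positions lining each binding-groove pocket of HLA-DR, and whether
# the pocket is an anchor (pockets 1, 4, 6, 7, 9 dominate binding specificity).
pocket	positions	is_anchor
1	82 85 86 89	TRUE
2	77 78 81 82	FALSE
3	78	FALSE
4	11 13 26 28 70 71 74 78	TRUE
5	11 13 28 70 71 74	FALSE
6	11 13 28 70 71 74	TRUE
7	11 28 30 47 61 67 70 71	TRUE
8	60 61	FALSE
9	9 30 37 57 60 61	TRUE
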