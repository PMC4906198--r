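# Observed pocket compositions of the 30 test-set HLA-DR complexes: the beta-chain
# residues (position + one-letter residue) seen lining each pocket in the solved
# structure. Observational data; the canonical pocket definitions live in
# pockets.tsv. Empty cells of the source table are omitted.
pdb_id	pocket	residues
1AQD	1	82N 85V 86G
1AQD	2	77T 78Y 81H 82N
1AQD	3	78Y
1AQD	4	13F 74A 78Y
1AQD	5	13F 71R
1AQD	6	11L
1AQD	7	47Y 61W 67L 70Q 71R
1AQD	8	60Y 61W
1AQD	9	9W 57D 61W
1PYW	1	82N 85V 86G 89F
1PYW	2	77T 78Y 81H 82N
1PYW	3	78Y
1PYW	4	13F 70Q 71R 74A 78Y
1PYW	5	13F 71R
1PYW	6	11L
1PYW	7	11L 28E 61W 71R
1PYW	8	60Y 61W
1PYW	9	57D 61W
1KLG	1	82N 85V
1KLG	2	78Y 81H 82N
1KLG	3	78Y
1KLG	4	13F 71R 78Y
1KLG	5	13F 71R
1KLG	6	11L
1KLG	7	61W
1KLG	8	60Y 61W
1KLG	9	57D 61W
2FSE	1	82N 85V 86G 89F
2FSE	2	77T 78Y 82N
2FSE	4	13F 28E 70Q 71R 74A 78Y
2FSE	5	13F 71R
2FSE	6	71R
2FSE	7	28E 47Y 61W 67L 71R
2FSE	8	61W
2FSE	9	57D
1KLU	1	82N 85V
1KLU	2	78Y 81H 82N
1KLU	4	13F 71R 78Y
1KLU	5	13F 71R
1KLU	6	11L
1KLU	7	61W
1KLU	8	60Y 61W
1KLU	9	57D 61W
1SJH	1	82N
1SJH	2	78Y 81H 82N
1SJH	4	13F 26L 70Q 71R 74A 78Y
1SJH	5	71R
1SJH	6	11L
1SJH	7	61W
1SJH	8	60Y 61W
1SJH	9	57D 61W
1SJE	1	82N
1SJE	2	78Y 81H 82N
1SJE	3	78Y
1SJE	4	13F 26L 70Q 71R 74A 78Y
1SJE	5	71R
1SJE	6	11L
1SJE	7	61W
1SJE	8	60Y 61W
1SJE	9	57D 60Y 61W
1T5W	1	82N 86G 89F
1T5W	2	78Y 81H 82N
1T5W	3	78Y
1T5W	4	13F 70Q 71R 74A 78Y
1T5W	5	13F 71R
1T5W	6	11L
1T5W	7	61W 71R
1T5W	8	60Y 61W
1T5W	9	9W 57D 61W
1T5X	1	82N 86G 89F
1T5X	2	78Y 81H 82N
1T5X	3	78Y
1T5X	4	13F 70Q 71R 74A 78Y
1T5X	5	71R
1T5X	6	11L
1T5X	7	61W 71R
1T5X	8	61W
1T5X	9	57D 61W
2IAN	1	82N 85V
2IAN	2	78Y 81H 82N
2IAN	3	78Y
2IAN	4	13F 70Q 74A 78Y
2IAN	5	13F 70Q 71R
2IAN	6	11L
2IAN	7	61W 71R
2IAN	8	61W
2IAN	9	57D 61W
2IPK	1	82N 85V 86G 89F
2IPK	2	77T 78Y 81H 82N
2IPK	4	13F 70Q 71R 74A 78Y
2IPK	5	71R
2IPK	6	11L
2IPK	7	47Y 61W 67L 71R
2IPK	8	60Y 61W
2IPK	9	9W 57D 61W
1FYT	1	82N 85V 86G 89F
1FYT	2	78Y 81H 82N
1FYT	3	78Y
1FYT	4	13F 70Q 71R 74A 78Y
1FYT	5	13F 71R
1FYT	6	11L
1FYT	7	28E 47Y 61W 67L 71R
1FYT	8	60Y 61W
1FYT	9	9W 57D 61W
1R5I	1	82N 85V 86G 89F
1R5I	2	77T 78Y 81H 82N
1R5I	3	78Y
1R5I	4	13F 70Q 71R 74A 78Y
1R5I	5	70Q 71R
1R5I	6	11L
1R5I	7	47Y 61W 67L 71R
1R5I	8	61W
1R5I	9	9W 57D 61W
1HXY	1	82N 85V 86G 89F
1HXY	2	78Y 81H 82N
1HXY	4	13F 70Q 71R 74A 78Y
1HXY	5	71R
1HXY	6	11L
1HXY	7	28E 47Y 61W 67L 71R
1HXY	8	60Y 61W
1HXY	9	9W 57D 61W
1JWM	1	82N 85V 86G 89F
1JWM	2	78Y 81H 82N
1JWM	3	78Y
1JWM	4	13F 70Q 71R 74A 78Y
1JWM	5	71R
1JWM	6	11L
1JWM	7	28E 47Y 61W 67L 71R
1JWM	8	61W
1JWM	9	57D 61W
1JWS	1	82N 85V 86G 89F
1JWS	2	78Y 81H 82N
1JWS	3	78Y
1JWS	4	13F 70Q 71R 74A 78Y
1JWS	5	13F 71R
1JWS	6	11L
1JWS	7	47Y 61W 67L 71R
1JWS	8	61W
1JWS	9	9W 57D 61W
1JWU	1	82N 85V 86G 89F
1JWU	2	78Y 81H 82N
1JWU	3	78Y
1JWU	4	13F 70Q 71R 74A 78Y
1JWU	5	13F 71R
1JWU	6	11L
1JWU	7	28E 47Y 61W 67L 71R
1JWU	8	61W
1JWU	9	9W 57D 61W
1LO5	1	82N 85V 86G 89F
1LO5	2	78Y 81H 82N
1LO5	3	78Y
1LO5	4	13F 70Q 78Y
1LO5	5	13F 71R
1LO5	6	11L
1LO5	7	47Y 61W 67L 71R
1LO5	8	61W
1LO5	9	9W 57D 60Y 61W
2ICW	1	82N 85V 86G 89F
2ICW	2	78Y 81H 82N
2ICW	3	78Y
2ICW	4	13F 70Q 71R 74A 78Y
2ICW	5	13F 71R
2ICW	6	11L
2ICW	7	28E 47Y 61W 67L 71R
2ICW	8	61W
2ICW	9	9W 57D 61W
2OJE	1	82N 85V 86G
2OJE	2	77T 78Y 81H 82N
2OJE	3	78Y
2OJE	4	13F 70Q 71R 74A 78Y
2OJE	5	70Q 71R
2OJE	6	11L
2OJE	7	28E 47Y 61W 67L 71R
2OJE	8	61W
2OJE	9	9W 57D 61W
2G9H	1	82N 85V 86G 89F
2G9H	2	77T 78Y 81H 82N
2G9H	3	78Y
2G9H	4	13F 70Q 71R 74A 78Y
2G9H	5	71R
2G9H	6	11L 13F
2G9H	7	28E 47Y 61W 67L 71R
2G9H	8	60Y 61W
2G9H	9	9W 57D 61W
2IAM	1	82N
2IAM	2	78Y 81H 82N
2IAM	3	78Y
2IAM	4	13F 70Q 71R 74A 78Y
2IAM	5	70Q 71R
2IAM	6	11L
2IAM	7	61W 67L 71R
2IAM	8	60Y 61W
2IAM	9	57D 61W
1A6A	1	82N 85V 86V
1A6A	2	77T 78Y 81H 82N
1A6A	3	78Y
1A6A	4	13S 26Y 74R 78Y
1A6A	5	71K 74R
1A6A	6	11S 30Y
1A6A	7	30Y 47F 61W 67L 71K
1A6A	8	61W
1A6A	9	9E 30Y 57D 61W
1J8H	1	82N 85V 86G 89F
1J8H	2	77T 78Y 81H 82N
1J8H	3	78Y
1J8H	4	13H 26F 28D 70Q 74A 78Y
1J8H	5	13H 70Q 71K
1J8H	6	11V 13H 30Y
1J8H	7	30Y 47Y 61W 67L
1J8H	8	60Y 61W
1J8H	9	37Y 57D 61W
2SEB	1	82N
2SEB	2	77T 78Y 81H 82N
2SEB	4	13H 26F 71K 78Y
2SEB	5	13H 71K
2SEB	6	30Y
2SEB	7	30Y 47Y 61W
2SEB	8	60Y 61W
2SEB	9	61W
1BX2	1	82N 85V
1BX2	2	77T 78Y 81H 82N
1BX2	3	78Y
1BX2	4	13H 26F 28D 70Q 74A 78Y
1BX2	5	70Q
1BX2	6	13R
1BX2	9	57D 60Y 61W
1YMM	1	82N
1YMM	2	77T 78Y 81H 82N
1YMM	3	78Y
1YMM	4	13R 26F 28D 70Q 74A 78Y
1YMM	5	70Q
1YMM	6	13R
1YMM	7	61W 67I
1YMM	8	61W
1YMM	9	57D 61W
1FV1	1	82N 85V 86G 89F
1FV1	2	78Y 81H 82N
1FV1	3	78Y
1FV1	4	13Y 71R 78Y
1FV1	5	71R
1FV1	6	13Y
1FV1	7	61W 67L 71K
1FV1	8	61W
1FV1	9	57D
1H15	1	82N 89F
1H15	2	77T 78Y 81H 82N
1H15	3	78Y
1H15	4	13Y 71R 78Y
1H15	5	71R
1H15	6	11D 13Y 30D
1H15	7	61W
1H15	9	57D 60Y
1ZGL	1	82N 85V 89F
1ZGL	2	77T 78Y 81H 82N
1ZGL	4	13Y 26F 71R 78Y
1ZGL	5	13Y
1ZGL	6	13Y 28H 61W 71R
1ZGL	7	61W
1ZGL	9	57D 60Y 61W
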