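# Published per-complex binding-core predictions, long format.
# method "published" = the pocket-similarity profile-synthesis method this package
# reimplements (as listed by its authors, K1 scoring, alpha = 3); the other
# methods are competitor tools whose predictions are shipped as static reference
# data only. Competitor columns exist for the 30-complex test set; the 9 held-out
# complexes carry only the "published" predictions.
pdb_id	method	predicted_core
1AQD	published	WRFLRGYHQ
1PYW	published	FVKQNAAAL
1KLG	published	IGILNAAKV
2FSE	published	IGTLNAAKV
1KLU	published	FKGEQGPKG
1SJH	published	VIPMFSALS
1SJE	published	VIPMFSALS
1T5W	published	SDQATPLLL
1T5X	published	SDQATPLLL
2IAN	published	IGTLNAAKV
2IPK	published	IGILNAAKV
1FYT	published	WVKQNTLKL
1R5I	published	YVKQNTLKL
1HXY	published	YVKQNTLKL
1JWM	published	YVKQNTLKL
1JWS	published	YVKQNTLKL
1JWU	published	YVKQNTLKL
1LO5	published	YVKQNTLKL
2ICW	published	YVKQNTLKL
2OJE	published	YVKQNTLKL
2G9H	published	YVKQNTLKL
2IAM	published	YVKQNTLKL
1A6A	published	MRMATPLLM
1J8H	published	YVKQNTLKL
2SEB	published	MRADAAAGG
1BX2	published	VHFFKNIVT
1YMM	published	VHFFKNIVT
1FV1	published	KNIVTPRTP
1H15	published	YHFVKKHVH
1ZGL	published	KNIVTPRTP
1AQD	TEPITOPE	WRFLRGYHQ
1PYW	TEPITOPE	FVKQNAAAL
1KLG	TEPITOPE	IGILNAAKV
2FSE	TEPITOPE	IGTLNAAKV
1KLU	TEPITOPE	FKGEQGPKG
1SJH	TEPITOPE	VIPMFSALS
1SJE	TEPITOPE	VIPMFSALS
1T5W	TEPITOPE	YSDQATPLL
1T5X	TEPITOPE	YSDQATPLL
2IAN	TEPITOPE	IGTLNAAKV
2IPK	TEPITOPE	IGILNAAKV
1FYT	TEPITOPE	WVKQNTLKL
1R5I	TEPITOPE	YVKQNTLKL
1HXY	TEPITOPE	YVKQNTLKL
1JWM	TEPITOPE	YVKQNTLKL
1JWS	TEPITOPE	YVKQNTLKL
1JWU	TEPITOPE	YVKQNTLKL
1LO5	TEPITOPE	YVKQNTLKL
2ICW	TEPITOPE	YVKQNTLKL
2OJE	TEPITOPE	YVKQNTLKL
2G9H	TEPITOPE	YVKQNTLKL
2IAM	TEPITOPE	YVKQNTLKL
1A6A	TEPITOPE	MRMATPLLM
1J8H	TEPITOPE	YVKQNTLKL
2SEB	TEPITOPE	MRADAAAGG
1BX2	TEPITOPE	VHFFKNIVT
1YMM	TEPITOPE	VHFFKNIVT
1FV1	TEPITOPE	FKNIVTPRT
1H15	TEPITOPE	YHFVKKHVH
1ZGL	TEPITOPE	FKNIVTPRT
1AQD	MultiRTA	WRFLRGYHQ
1PYW	MultiRTA	FVKQNAAAL
1KLG	MultiRTA	IGILNAAKV
2FSE	MultiRTA	IGTLNAAKV
1KLU	MultiRTA	FKGEQGPKG
1SJH	MultiRTA	VIPMFSALS
1SJE	MultiRTA	VIPMFSALS
1T5W	MultiRTA	SDQATPLLL
1T5X	MultiRTA	SDQATPLLL
2IAN	MultiRTA	IGTLNAAKV
2IPK	MultiRTA	IGILNAAKV
1FYT	MultiRTA	WVKQNTLKL
1R5I	MultiRTA	YVKQNTLKL
1HXY	MultiRTA	YVKQNTLKL
1JWM	MultiRTA	YVKQNTLKL
1JWS	MultiRTA	YVKQNTLKL
1JWU	MultiRTA	YVKQNTLKL
1LO5	MultiRTA	YVKQNTLKL
2ICW	MultiRTA	YVKQNTLKL
2OJE	MultiRTA	YVKQNTLKL
2G9H	MultiRTA	YVKQNTLKL
2IAM	MultiRTA	YVKQNTLKL
1A6A	MultiRTA	MRMATPLLM
1J8H	MultiRTA	YVKQNTLKL
2SEB	MultiRTA	MRADAAAGG
1BX2	MultiRTA	VHFFKNIVT
1YMM	MultiRTA	VHFFKNIVT
1FV1	MultiRTA	VHFFKNIVT
1H15	MultiRTA	YHFVKKHVH
1ZGL	MultiRTA	VHFFKNIVT
1AQD	NetMHCIIpan-2.0	WRFLRGYHQ
1PYW	NetMHCIIpan-2.0	FVKQNAAAL
1KLG	NetMHCIIpan-2.0	LIGILNAAK
2FSE	NetMHCIIpan-2.0	IGTLNAAKV
1KLU	NetMHCIIpan-2.0	FKGEQGPKG
1SJH	NetMHCIIpan-2.0	VIPMFSALS
1SJE	NetMHCIIpan-2.0	VIPMFSALS
1T5W	NetMHCIIpan-2.0	YSDQATPLL
1T5X	NetMHCIIpan-2.0	YSDQATPLL
2IAN	NetMHCIIpan-2.0	IGTLNAAKV
2IPK	NetMHCIIpan-2.0	LIGILNAAK
1FYT	NetMHCIIpan-2.0	WVKQNTLKL
1R5I	NetMHCIIpan-2.0	YVKQNTLKL
1HXY	NetMHCIIpan-2.0	YVKQNTLKL
1JWM	NetMHCIIpan-2.0	YVKQNTLKL
1JWS	NetMHCIIpan-2.0	YVKQNTLKL
1JWU	NetMHCIIpan-2.0	YVKQNTLKL
1LO5	NetMHCIIpan-2.0	YVKQNTLKL
2ICW	NetMHCIIpan-2.0	YVKQNTLKL
2OJE	NetMHCIIpan-2.0	YVKQNTLKL
2G9H	NetMHCIIpan-2.0	YVKQNTLKL
2IAM	NetMHCIIpan-2.0	YVKQNTLKL
1A6A	NetMHCIIpan-2.0	MRMATPLLM
1J8H	NetMHCIIpan-2.0	YVKQNTLKL
2SEB	NetMHCIIpan-2.0	YMRADAAAG
1BX2	NetMHCIIpan-2.0	VVHFFKNIV
1YMM	NetMHCIIpan-2.0	VHFFKNIVT
1FV1	NetMHCIIpan-2.0	FFKNIVTPR
1H15	NetMHCIIpan-2.0	YHFVKKHVH
1ZGL	NetMHCIIpan-2.0	FFKNIVTPR
4E41	published	IGILNAAKV
1DLH	published	YVKQNTLKL
1KG0	published	YVKQNTLKL
3L6F	published	YEKLSAEQS
3PDO	published	KMRMATPLL
3PGD	published	MRMATPLLM
3S4S	published	YVKQNTLKL
3S5L	published	YVKQNTLKL
1HQR	published	FKNIVTPRT
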