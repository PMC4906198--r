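# The eleven reference HLA-DR alleles whose quantitative pocket profiles anchor
# pan-specific profile synthesis (TEPITOPE-style registry skeleton). The
# quantitative matrices themselves are not redistributable and ship empty;
# users holding published TEPITOPE pocket matrices can load them through
# read_profile_registry() to populate a working registry.
allele	pseudoseq_p4	pseudoseq_p6	pseudoseq_p7	pseudoseq_p9
DRB1*0101				
DRB1*0301				
DRB1*0401				
DRB1*0402				
DRB1*0404				
DRB1*0701				
DRB1*0801				
DRB1*1101				
DRB1*1302				
DRB1*1501				
DRB5*0101				
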