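gene,snp_id,group,major_allele,minor_allele,n_major_homo,n_het,n_minor_homo,count_major_printed,count_minor_printed,allele_p_printed,hwe_p_printed
LEPR,rs1137101,overall,A,G,190,273,154,653,581,NA,0.006
LEPR,rs1137101,overweight_obese,A,G,52,86,33,190,152,0.189,0.88
LEPR,rs1137101,normal_weight,A,G,115,165,105,395,375,NA,0.0058
FTO,rs9939609,overall,T,A,159,259,112,557,483,NA,0.73
FTO,rs9939609,overweight_obese,T,A,86,137,68,183,151,0.75,0.88
FTO,rs9939609,normal_weight,T,A,93,160,69,346,298,NA,1.00
MC4R,rs2229616,overall,G,A,428,9,0,865,9,NA,1.00
MC4R,rs2229616,overweight_obese,G,A,120,2,0,242,2,0.600,1.00
MC4R,rs2229616,normal_weight,G,A,275,7,0,557,7,NA,1.00
MC4R,rs17782313,overall,T,C,222,110,20,554,150,NA,0.2
MC4R,rs17782313,overweight_obese,T,C,76,34,4,186,42,0.26,1.00
MC4R,rs17782313,normal_weight,T,C,132,66,14,330,94,NA,0.16
PPARG,rs1801282,overall,C,G,225,45,2,495,44,NA,1.00
PPARG,rs1801282,overweight_obese,C,G,58,15,0,131,15,0.539,1.00
PPARG,rs1801282,normal_weight,C,G,157,28,2,342,32,NA,0.63
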