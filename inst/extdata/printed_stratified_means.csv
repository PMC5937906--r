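gene,snp_id,stratum,genotype_class,variable,n,mean,sd
LEPR,rs1137101,overweight_obese,major_homo,bmi,76,23.29,2.52
LEPR,rs1137101,overweight_obese,het,bmi,127,23.58,2.73
LEPR,rs1137101,overweight_obese,minor_homo,bmi,50,23.18,2.29
LEPR,rs1137101,normal_weight,major_homo,bmi,107,16.95,1.66
LEPR,rs1137101,normal_weight,het,bmi,138,16.89,1.62
LEPR,rs1137101,normal_weight,minor_homo,bmi,99,16.59,1.81
LEPR,rs1137101,overweight_obese,major_homo,zbmi,76,2.11,0.47
LEPR,rs1137101,overweight_obese,het,zbmi,127,2.14,0.47
LEPR,rs1137101,overweight_obese,minor_homo,zbmi,50,2.07,0.47
LEPR,rs1137101,normal_weight,major_homo,zbmi,107,0.15,0.78
LEPR,rs1137101,normal_weight,het,zbmi,138,0.13,0.76
LEPR,rs1137101,normal_weight,minor_homo,zbmi,99,-0.05,0.87
FTO,rs9939609,overweight_obese,major_homo,bmi,86,22.81,2.25
FTO,rs9939609,overweight_obese,het,bmi,137,22.89,2.74
FTO,rs9939609,overweight_obese,minor_homo,bmi,68,23.24,2.33
FTO,rs9939609,normal_weight,major_homo,bmi,69,16.85,1.54
FTO,rs9939609,normal_weight,het,bmi,119,16.99,1.49
FTO,rs9939609,normal_weight,minor_homo,bmi,42,16.56,1.43
FTO,rs9939609,overweight_obese,major_homo,zbmi,86,2.05,0.42
FTO,rs9939609,overweight_obese,het,zbmi,137,2.04,0.46
FTO,rs9939609,overweight_obese,minor_homo,zbmi,68,2.12,0.40
FTO,rs9939609,normal_weight,major_homo,zbmi,69,0.16,0.74
FTO,rs9939609,normal_weight,het,zbmi,119,0.24,0.71
FTO,rs9939609,normal_weight,minor_homo,zbmi,42,0.02,0.72
MC4R,rs2229616,overweight_obese,major_homo,bmi,226,23.40,2.77
MC4R,rs2229616,overweight_obese,het,bmi,5,24.05,0.93
MC4R,rs2229616,overweight_obese,minor_homo,bmi,0,NA,NA
MC4R,rs2229616,normal_weight,major_homo,bmi,199,16.59,1.51
MC4R,rs2229616,normal_weight,het,bmi,4,16.25,1.48
MC4R,rs2229616,normal_weight,minor_homo,bmi,0,NA,NA
MC4R,rs2229616,overweight_obese,major_homo,zbmi,226,2.15,0.46
MC4R,rs2229616,overweight_obese,het,zbmi,5,2.29,0.19
MC4R,rs2229616,overweight_obese,minor_homo,zbmi,0,NA,NA
MC4R,rs2229616,normal_weight,major_homo,zbmi,199,0.04,0.73
MC4R,rs2229616,normal_weight,het,zbmi,4,-0.10,0.70
MC4R,rs2229616,normal_weight,minor_homo,zbmi,0,NA,NA
MC4R,rs17782313,overweight_obese,major_homo,bmi,140,23.92,2.75
MC4R,rs17782313,overweight_obese,het,bmi,77,22.69,2.11
MC4R,rs17782313,overweight_obese,minor_homo,bmi,15,23.89,4.21
MC4R,rs17782313,normal_weight,major_homo,bmi,80,16.74,1.37
MC4R,rs17782313,normal_weight,het,bmi,32,16.85,1.77
MC4R,rs17782313,normal_weight,minor_homo,bmi,4,16.55,1.49
MC4R,rs17782313,overweight_obese,major_homo,zbmi,140,2.22,0.47
MC4R,rs17782313,overweight_obese,het,zbmi,77,2.03,0.40
MC4R,rs17782313,overweight_obese,minor_homo,zbmi,15,2.26,0.50
MC4R,rs17782313,normal_weight,major_homo,zbmi,80,0.13,0.66
MC4R,rs17782313,normal_weight,het,zbmi,32,0.11,0.78
MC4R,rs17782313,normal_weight,minor_homo,zbmi,4,0.04,0.76
PPARG,rs1801282,overweight_obese,major_homo,bmi,64,22.04,2.16
PPARG,rs1801282,overweight_obese,het,bmi,12,21.42,1.18
PPARG,rs1801282,overweight_obese,minor_homo,bmi,0,NA,NA
PPARG,rs1801282,normal_weight,major_homo,bmi,140,16.82,1.55
PPARG,rs1801282,normal_weight,het,bmi,33,16.46,1.58
PPARG,rs1801282,normal_weight,minor_homo,bmi,2,17.87,0.19
PPARG,rs1801282,overweight_obese,major_homo,zbmi,64,1.95,0.41
PPARG,rs1801282,overweight_obese,het,zbmi,12,1.79,0.28
PPARG,rs1801282,overweight_obese,minor_homo,zbmi,0,NA,NA
PPARG,rs1801282,normal_weight,major_homo,zbmi,140,0.23,0.72
PPARG,rs1801282,normal_weight,het,zbmi,33,0.02,0.80
PPARG,rs1801282,normal_weight,minor_homo,zbmi,2,0.90,0.00
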