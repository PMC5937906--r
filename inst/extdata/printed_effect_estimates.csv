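gene,snp_id,variable,dominant_effect,additive_effect,population_mean,minor_avg_effect,aecme,dominance_type,effect_grade
LEPR,rs1137101,bmi,0.52,-0.43,18.56,-0.25,-0.48,NA,NA
FTO,rs9939609,bmi,-0.01,0.12,18.70,0.06,0.12,NA,NA
MC4R,rs17782313,bmi,0.05,-0.54,18.37,-0.12,-0.57,NA,NA
PPARG,rs1801282,bmi,1.45,-1.15,18.30,-0.21,-2.34,NA,NA
LEPR,rs1137101,zbmi,0.28,-0.15,0.81,-0.09,-0.17,overdominance,weak decrease
FTO,rs9939609,zbmi,-0.07,0.06,1.27,0.03,0.06,complete_dominance,very weak increase
MC4R,rs17782313,zbmi,-0.16,0.17,1.63,0.06,0.26,complete_dominance,weak increase
PPARG,rs1801282,zbmi,0.68,-1.12,1.24,-0.15,-1.68,partial_dominance,medium decrease
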