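participant_id,group,amputation_level,side,deprivation_age,cosmetic_prosthesis_usage,functional_prosthesis_usage,mal_score,pain_intensity,pain_frequency,laterality_index,beta_intact_hand,beta_residual_arm
C01,congenital,4,L,0,5,0,0.61,2,4,0.21,0.35,1.42
A01,acquired,4,L,38,2,0,0.31,6,2,0.74,1.28,0.22
N01,control,,,,,,,,,,0.48,0.55
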