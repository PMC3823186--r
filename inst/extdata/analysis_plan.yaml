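# Cohort analysis plan: steps run in order by run_cohort_analysis().
# Planned comparisons are tested at alpha = 0.025 (two pre-specified tests
# per limb); everything else at 0.05.  Filters are expressions over cohort
# columns; arm contrasts exclude above-elbow deprivation declaratively.
- name: li_vs_zero_congenital
  type: one_sample
  dv: laterality_index
  group: congenital
- name: li_vs_zero_acquired
  type: one_sample
  dv: laterality_index
  group: acquired
- name: li_group_comparison
  type: two_sample
  dv: laterality_index
  groups: [acquired, congenital]
- name: mal_group_comparison
  type: two_sample
  dv: mal_score
  groups: [congenital, acquired]
- name: mal_group_adjusted
  type: covariate_contrast
  dv: mal_score
  groups: [congenital, acquired]
  covariates: [amputation_level, functional_prosthesis_usage, cosmetic_prosthesis_usage]
- name: mal_vs_li
  type: pearson
  x: mal_score
  y: laterality_index
  filter: group != "control"
- name: mal_vs_li_partial
  type: partial
  x: mal_score
  y: laterality_index
  nuisance: [amputation_level, functional_prosthesis_usage, cosmetic_prosthesis_usage]
  alternative: less
  filter: group != "control"
- name: beta_mixed_anova
  type: mixed_anova
  dv_cols: [beta_intact_hand, beta_residual_arm]
- name: hand_beta_acquired_vs_congenital
  type: two_sample
  dv: beta_intact_hand
  groups: [acquired, congenital]
  planned: true
- name: hand_beta_acquired_vs_control
  type: two_sample
  dv: beta_intact_hand
  groups: [acquired, control]
  planned: true
- name: arm_beta_congenital_vs_acquired
  type: two_sample
  dv: beta_residual_arm
  groups: [congenital, acquired]
  planned: true
  filter: is.na(amputation_level) | amputation_level >= 3
- name: arm_beta_congenital_vs_control
  type: two_sample
  dv: beta_residual_arm
  groups: [congenital, control]
  planned: true
  filter: is.na(amputation_level) | amputation_level >= 3
- name: usage_vs_hand_beta
  type: pearson
  x: mal_score
  y: beta_intact_hand
  filter: group != "control"
- name: usage_vs_hand_beta_partial
  type: partial
  x: mal_score
  y: beta_intact_hand
  nuisance: [deprivation_age]
  alternative: less
  filter: group != "control"
- name: usage_vs_hand_beta_prosthesis_users
  type: pearson
  x: mal_score
  y: beta_intact_hand
  filter: group != "control" & (functional_prosthesis_usage > 0 | cosmetic_prosthesis_usage > 0)
- name: pain_vs_usage_acquired
  type: pearson
  x: chronic_pain
  y: mal_score
  filter: group == "acquired"
- name: hand_beta_pain_adjusted
  type: covariate_contrast
  dv: beta_intact_hand
  groups: [acquired, congenital]
  covariates: [chronic_pain]
- name: corr_users_vs_all
  type: fisher
  ref1: usage_vs_hand_beta_prosthesis_users
  ref2: usage_vs_hand_beta
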