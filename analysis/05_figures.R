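#!/usr/bin/env Rscript
# Step 5: summary figures for the simulated cohort (written under
# results/figures/): laterality index by group, questionnaire score against
# laterality, group-by-limb activation means, and the usage-activation
# scatter.

suppressPackageStartupMessages({
  library(limbuse)
  library(ggplot2)
})

co <- read_cohort("results/cohort.csv")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
oh <- co[co$group != "control", ]

p1 <- ggplot(oh, aes(group, laterality_index, fill = group)) +
  geom_boxplot(alpha = 0.6, outlier.shape = NA) +
  geom_jitter(width = 0.12, size = 1.6) +
  geom_hline(yintercept = 0, linetype = 2) +
  labs(y = "movement laterality index\n(+1 = intact hand only)", x = NULL,
       title = "Habitual limb use by group") +
  theme_classic() + theme(legend.position = "none")
ggsave("results/figures/laterality_by_group.pdf", p1, width = 4, height = 4)

p2 <- ggplot(oh, aes(mal_score, laterality_index, colour = group)) +
  geom_point(size = 2) + geom_smooth(method = "lm", se = FALSE, colour = "grey30") +
  labs(x = "residual-arm usage score (MAL, 0-1)",
       y = "movement laterality index",
       title = "Questionnaire vs accelerometry") +
  theme_classic()
ggsave("results/figures/mal_vs_laterality.pdf", p2, width = 5, height = 4)

beta_long <- rbind(
  data.frame(group = co$group, limb = "intact hand", beta = co$beta_intact_hand),
  data.frame(group = co$group, limb = "residual arm", beta = co$beta_residual_arm)
)
p3 <- ggplot(beta_long, aes(group, beta, fill = limb)) +
  stat_summary(fun = mean, geom = "col", position = position_dodge(0.9), alpha = 0.8) +
  stat_summary(fun.data = mean_se, geom = "errorbar",
               position = position_dodge(0.9), width = 0.25) +
  labs(y = "deprived-cortex activation (beta, a.u.)", x = NULL,
       title = "Group-by-limb activation") +
  theme_classic()
ggsave("results/figures/beta_group_by_limb.pdf", p3, width = 5.5, height = 4)

p4 <- ggplot(oh, aes(mal_score, beta_intact_hand, colour = group)) +
  geom_point(size = 2) + geom_smooth(method = "lm", se = FALSE, colour = "grey30") +
  labs(x = "residual-arm usage score (MAL, 0-1)",
       y = "intact-hand activation (beta, a.u.)",
       title = "Usage vs intact-hand activation") +
  theme_classic()
ggsave("results/figures/usage_vs_activation.pdf", p4, width = 5, height = 4)

cat("Wrote 4 figures to results/figures/\n")
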