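test_that("gated two-sample comparison gates on Shapiro-Wilk and reports its branch", {
  r <- gated_two_sample(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$test_name, "student_t")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$details$branch, "parametric")

  # forced nonparametric branch with complete separation: minimal rank sum
  r2 <- gated_two_sample(c(1, 2, 3), c(4, 5, 6), branch = "nonparametric")
  expect_equal(r2$test_name, "mann_whitney")
  expect_equal(unname(r2$statistic), 0)

  # the branch is a pure function of the Shapiro-Wilk p-values
  set.seed(31)
  a <- rnorm(15); b <- c(rnorm(14), 40)  # gross outlier forces non-normality
  r3 <- gated_two_sample(a, b)
  expect_equal(r3$details$branch, "nonparametric")
  expect_true(all(is.finite(r3$details$shapiro_p)))
  expect_equal(r3$details$branch == "nonparametric",
               any(r3$details$shapiro_p <= 0.05))

  expect_error(gated_two_sample(c(1, 1, 1, 1), rnorm(5)), "zero variance")
})

test_that("two-sample statistics agree with textbook formulas", {
  set.seed(12)
  a <- rnorm(12, 0.3); b <- rnorm(9)
  r <- gated_two_sample(a, b, branch = "parametric")
  o <- oracle_pooled_t(a, b)
  expect_equal(unname(r$statistic), o$t, tolerance = 1e-10)
  expect_equal(unname(r$df), o$df)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)

  a2 <- c(0.1, 0.9, 1.7, 2.2); b2 <- c(0.4, 1.1, 1.5)
  r2 <- gated_two_sample(a2, b2, branch = "nonparametric")
  o2 <- oracle_mann_whitney(a2, b2)
  expect_equal(unname(r2$statistic), o2$U, tolerance = 1e-10)
  expect_equal(r2$p_value, o2$p, tolerance = 1e-10)
})

test_that("one-sample test against zero matches its closed form", {
  x <- c(-2, -1, 0, 1, 2)
  r <- one_sample_vs_zero(x)
  expect_equal(unname(r$statistic), 0)
  expect_error(one_sample_vs_zero(c(1, 1, 1, 1)), "zero variance")

  set.seed(77)
  y <- rnorm(20, 0.4)
  o <- oracle_one_sample_t(y)
  r2 <- one_sample_vs_zero(y)
  expect_equal(unname(r2$statistic), o$t, tolerance = 1e-10)
  expect_equal(r2$p_value, o$p, tolerance = 1e-10)
})

make_toy_cohort <- function(beta_intact, beta_residual, groups) {
  n <- length(groups)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)), group = groups,
    amputation_level = ifelse(groups == "control", NA, 4), side = ifelse(groups == "control", NA, "L"),
    deprivation_age = ifelse(groups == "control", NA, 0),
    cosmetic_prosthesis_usage = NA, functional_prosthesis_usage = NA,
    mal_score = NA, pain_intensity = NA, pain_frequency = NA,
    laterality_index = NA,
    beta_intact_hand = beta_intact, beta_residual_arm = beta_residual
  )
}

test_that("mixed ANOVA interaction is null when cell means carry no interaction", {
  groups <- rep(c("congenital", "acquired", "control"), each = 4)
  subj <- c(0.3, -0.1, 0.2, 0.05, 0.4, -0.2, 0.1, 0, -0.3, 0.2, 0.15, -0.05)
  mu_g <- c(congenital = 1, acquired = 2, control = 3)[groups]
  # within-cell noise centred per group-by-limb cell keeps the cell means,
  # and hence the interaction, exactly null while the error SS stays positive
  set.seed(61)
  noise <- function() {
    e <- rnorm(12)
    as.numeric(e - ave(e, groups))
  }
  co <- make_toy_cohort(mu_g + subj + 0.5 + noise(), mu_g + subj - 0.5 + noise(),
                        groups)
  r <- mixed_anova(co)
  expect_lt(abs(unname(r$statistic)), 1e-10)
})

test_that("mixed ANOVA interaction F equals the long-hand sums-of-squares decomposition", {
  set.seed(21)
  groups <- rep(c("congenital", "acquired", "control"), each = 4)
  co <- make_toy_cohort(rnorm(12), rnorm(12), groups)
  r <- mixed_anova(co)
  long <- data.frame(
    value = c(co$beta_intact_hand, co$beta_residual_arm),
    group = rep(groups, 2), subject = rep(co$participant_id, 2),
    limb = rep(c("intact", "residual"), each = 12)
  )
  o <- oracle_mixed_anova_F(long$value, long$group, long$subject, long$limb)
  expect_equal(unname(r$statistic), o$F, tolerance = 1e-10)
  expect_equal(unname(r$df), o$df)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
})

test_that("mixed ANOVA rejects incomplete within-participant data, naming participants", {
  groups <- rep(c("congenital", "acquired"), each = 3)
  co <- make_toy_cohort(rnorm(6), rnorm(6), groups)
  co$beta_residual_arm[2] <- NA
  expect_error(mixed_anova(co), co$participant_id[2])
})

test_that("covariate-adjusted contrast reduces to the unadjusted test and matches nested RSS", {
  set.seed(33)
  groups <- rep(c("congenital", "acquired"), each = 4)
  co <- make_toy_cohort(rnorm(8), rnorm(8), groups)
  co$cov1 <- rnorm(8); co$cov2 <- rnorm(8)

  r0 <- covariate_adjusted_contrast(co, "beta_intact_hand")
  a <- co$beta_intact_hand[groups == "congenital"]
  b <- co$beta_intact_hand[groups == "acquired"]
  o_t <- oracle_pooled_t(a, b)
  expect_equal(unname(r0$statistic), o_t$t^2, tolerance = 1e-10)

  # constant covariates contribute nothing
  co$const <- 1
  r_const <- covariate_adjusted_contrast(co, "beta_intact_hand", covariates = "const")
  expect_equal(unname(r_const$statistic), o_t$t^2, tolerance = 1e-10)

  r2 <- covariate_adjusted_contrast(co, "beta_intact_hand", covariates = c("cov1", "cov2"))
  o2 <- oracle_nested_F(co$beta_intact_hand, co$group, cbind(co$cov1, co$cov2))
  expect_equal(unname(r2$statistic), o2$F, tolerance = 1e-10)
  expect_equal(unname(r2$df), o2$df)
  expect_equal(r2$p_value, o2$p, tolerance = 1e-10)

  # dependent fully determined by a covariate: group effect vanishes
  co$dep <- 2 * co$cov1 + 1
  r3 <- covariate_adjusted_contrast(co, "dep", covariates = "cov1")
  expect_lt(abs(unname(r3$statistic)), 1e-10)

  co$cov3 <- 2 * co$cov1
  expect_error(covariate_adjusted_contrast(co, "beta_intact_hand",
                                           covariates = c("cov1", "cov3")),
               "collinear")
})

test_that("Pearson correlation matches the covariance formula and handles exact linearity", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(pearson_corr(x, 2 * x + 3)$statistic), 1)
  expect_equal(unname(pearson_corr(x, -x)$statistic), -1)
  expect_error(pearson_corr(x, rep(2, 5)), "zero variance")

  set.seed(44)
  u <- rnorm(25); v <- 0.4 * u + rnorm(25)
  r <- pearson_corr(u, v)
  o <- oracle_pearson(u, v)
  expect_equal(unname(r$statistic), o$r, tolerance = 1e-10)
  expect_equal(unname(r$df), o$df)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
})

test_that("partial correlation equals residual-regression correlation and degenerates safely", {
  # orthogonal nuisance: partial equals Pearson
  x <- c(2, 4, 1, 5, 3, 6)
  y <- c(1, 3, 2, 6, 4, 5)
  z <- rep(c(-1, 1), 3)
  set.seed(9)
  n <- 30
  xx <- rnorm(n); yy <- rnorm(n)
  zz <- rnorm(n)
  zz <- resid(lm(zz ~ xx + yy))  # construct nuisance orthogonal to both
  rp <- partial_corr(xx, yy, zz, alternative = "two.sided")
  expect_equal(unname(rp$statistic), unname(pearson_corr(xx, yy)$statistic),
               tolerance = 1e-10)

  # toy dataset against the explicit two-stage oracle
  r6 <- partial_corr(x, y, z, alternative = "less")
  o6 <- oracle_partial(x, y, z)
  expect_equal(unname(r6$statistic), o6$r, tolerance = 1e-10)
  expect_equal(unname(r6$df), o6$df)
  expect_equal(r6$p_value, o6$p_less, tolerance = 1e-10)

  expect_error(partial_corr(x, y, x, alternative = "less"), "identical to x or y")
  expect_warning(partial_corr(x, y, z), "two-tailed")
})

test_that("Fisher r-to-z comparison follows the closed form and is antisymmetric", {
  r0 <- fisher_compare(0.4, 30, 0.4, 30)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)

  r1 <- fisher_compare(0.5, 20, 0, 20)
  o1 <- oracle_fisher_z(0.5, 20, 0, 20)
  expect_equal(unname(r1$statistic), o1$z, tolerance = 1e-10)
  expect_equal(r1$p_value, o1$p, tolerance = 1e-10)

  r2 <- fisher_compare(0, 20, 0.5, 20)
  expect_equal(unname(r2$statistic), -unname(r1$statistic))
  expect_equal(r2$p_value, r1$p_value)

  expect_error(fisher_compare(1, 20, 0.5, 20), "undefined")
})

test_that("planned comparisons apply alpha = 0.025 and exploratory contrasts 0.05", {
  # construct two groups whose pooled-t p-value lands between the two alphas
  find_groups <- function() {
    for (s in 1:200) {
      set.seed(s)
      a <- rnorm(12, 0.5); b <- rnorm(12)
      r <- gated_two_sample(a, b)
      if (r$details$branch == "parametric" &&
          r$p_value > 0.025 && r$p_value < 0.05) {
        return(list(a = a, b = b))
      }
    }
    stop("no suitable seed found")
  }
  g <- find_groups()
  co <- tibble::tibble(group = rep(c("g1", "g2"), each = 12), v = c(g$a, g$b))
  plan <- list(
    list(name = "planned", dv = "v", groups = c("g1", "g2"), planned = TRUE),
    list(name = "exploratory", dv = "v", groups = c("g1", "g2"))
  )
  res <- planned_comparisons(co, plan)
  expect_equal(res$planned$alpha_used, 0.025)
  expect_equal(res$planned$decision, "not_significant")
  expect_equal(res$exploratory$alpha_used, 0.05)
  expect_equal(res$exploratory$decision, "significant")

  # four-contrast bookkeeping
  plan4 <- lapply(1:4, function(i) list(name = paste0("c", i), dv = "v",
                                        groups = c("g1", "g2"),
                                        planned = i <= 2))
  res4 <- planned_comparisons(co, plan4)
  expect_length(res4, 4L)
  expect_equal(vapply(res4, function(r) r$alpha_used, 0),
               c(c1 = 0.025, c2 = 0.025, c3 = 0.05, c4 = 0.05))

  expect_error(planned_comparisons(co, list(list(name = "bad", dv = "v",
                                                 groups = c("g1", "nope")))),
               "unknown group")
})

test_that("stat_result decisions are consistent with p-value and alpha", {
  r <- stat_result("demo", 1.5, 10, p_value = 0.03, alpha_used = 0.05)
  expect_equal(r$decision, "significant")
  r2 <- stat_result("demo", 1.5, 10, p_value = 0.03, alpha_used = 0.025)
  expect_equal(r2$decision, "not_significant")
  expect_error(stat_result("demo", 1, 1, p_value = 1.2), "p_value")
  tab <- stat_results_table(list(a = r, b = r2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$decision, c("significant", "not_significant"))
})
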