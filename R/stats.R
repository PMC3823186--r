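#' Container for one statistical test result
#'
#' Every test in the cohort analysis battery returns a `stat_result`
#' recording which test was actually run (the gated tests can branch), the
#' statistic, degrees of freedom, p-value, tails, the alpha applied
#' (0.05 for exploratory tests, 0.025 for planned comparisons), and the
#' resulting decision.
#'
#' @param test_name Label of the test actually used (e.g. `"student_t"`,
#'   `"mann_whitney"`).
#' @param statistic Test statistic value (for correlations, the correlation
#'   coefficient; the t statistic is kept in `details`).
#' @param df Degrees of freedom: a single number, a pair (for F), or `NA`.
#' @param p_value Probability in \[0, 1\].
#' @param tails `"two"` or `"one"`.
#' @param alpha_used Significance level applied (0.05 or 0.025 under the
#'   analysis plan).
#' @param n_used Number of observations entering the test.
#' @param details Named list of extras (branch taken, normality p-values,
#'   exclusions, ...).
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, df, p_value, tails = c("two", "one"),
                        alpha_used = 0.05, n_used = NA_integer_, details = list()) {
  tails <- match.arg(tails)
  if (!is.finite(p_value) || p_value < 0 || p_value > 1) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(test_name = test_name, statistic = unname(statistic), df = unname(df),
         p_value = p_value, tails = tails, alpha_used = alpha_used,
         decision = if (p_value <= alpha_used) "significant" else "not_significant",
         n_used = n_used, details = details),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  df_str <- if (all(is.na(x$df))) "" else paste0("(", paste(round(x$df, 2), collapse = ","), ")")
  cat(sprintf("<stat_result> %s%s = %.4g, p = %.4g [%s-tailed, alpha = %g] -> %s (n = %s)\n",
              x$test_name, df_str, x$statistic, x$p_value, x$tails,
              x$alpha_used, x$decision, x$n_used))
  invisible(x)
}

#' Collect stat_results into a table
#'
#' @param results A list of [stat_result()] objects (optionally named; a
#'   `label` column is taken from the names).
#' @return A [tibble::tibble()], one row per result.
#' @export
stat_results_table <- function(results) {
  if (inherits(results, "stat_result")) results <- list(results)
  labels <- names(results)
  if (is.null(labels)) labels <- rep("", length(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble::tibble(
      label = labels[i],
      test_name = r$test_name,
      statistic = r$statistic,
      df = paste(round(r$df, 3), collapse = ","),
      p_value = r$p_value,
      tails = r$tails,
      alpha_used = r$alpha_used,
      decision = r$decision,
      n_used = r$n_used,
      notes = if (length(r$details)) {
        paste(names(r$details),
              vapply(r$details, function(d) paste(format(unlist(d), digits = 4), collapse = "/"), ""),
              sep = "=", collapse = "; ")
      } else ""
    )
  })
  do.call(rbind, rows)
}

.drop_na <- function(x) x[is.finite(x)]

#' Normality-gated two-sample comparison
#'
#' Runs a Shapiro-Wilk normality test on each group at the 0.05 level.  If
#' neither group departs significantly from normality, an independent
#' two-tailed Student t-test (pooled variance) is used; otherwise a
#' Mann-Whitney U test.  The branch taken is a pure function of the two
#' Shapiro-Wilk p-values and is recorded in `details`; either branch can be
#' forced for testing.
#'
#' Mann-Whitney p-values are exact when the combined sample size is at most
#' 20 and there are no ties, and use the tie-corrected normal approximation
#' otherwise.
#'
#' @param group_a,group_b Numeric samples (each needs >= 3 finite values).
#' @param alpha Significance level applied to the comparison (0.05, or 0.025
#'   for a planned comparison).
#' @param branch `"auto"` (Shapiro-Wilk gate), `"parametric"` or
#'   `"nonparametric"`.
#' @param var_equal Use the pooled-variance Student t (default `TRUE`); the
#'   Welch test is available as an option.
#' @return A [stat_result()]; `details` carries `branch`, `shapiro_p` and the
#'   group sizes.
#' @export
gated_two_sample <- function(group_a, group_b, alpha = 0.05,
                             branch = c("auto", "parametric", "nonparametric"),
                             var_equal = TRUE) {
  branch <- match.arg(branch)
  a <- .drop_na(group_a); b <- .drop_na(group_b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 finite values", call. = FALSE)
  }
  shapiro_p <- c(NA_real_, NA_real_)
  if (branch == "auto") {
    if (stats::var(a) == 0 || stats::var(b) == 0) {
      stop("degenerate input: a group has zero variance; normality cannot be assessed",
           call. = FALSE)
    }
    shapiro_p <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
    branch <- if (all(shapiro_p > 0.05)) "parametric" else "nonparametric"
  }
  details <- list(branch = branch, shapiro_p = shapiro_p,
                  n = c(length(a), length(b)))
  if (branch == "parametric") {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      stop("degenerate input: both groups have zero variance", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    stat_result(if (var_equal) "student_t" else "welch_t",
                statistic = tt$statistic, df = tt$parameter,
                p_value = tt$p.value, tails = "two", alpha_used = alpha,
                n_used = length(a) + length(b), details = details)
  } else {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 20L) && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = FALSE))
    details$exact <- exact
    stat_result("mann_whitney", statistic = wt$statistic, df = NA_real_,
                p_value = wt$p.value, tails = "two", alpha_used = alpha,
                n_used = length(a) + length(b), details = details)
  }
}

#' One-sample t-test against zero
#'
#' Tests whether a sample's mean differs from zero (e.g. a group's laterality
#' indices against balanced use).
#'
#' @param values Numeric sample, n >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param alpha Significance level.
#' @return A [stat_result()] with the t statistic and `df = n - 1`.
#' @export
one_sample_vs_zero <- function(values, alternative = c("two.sided", "greater", "less"),
                               alpha = 0.05) {
  alternative <- match.arg(alternative)
  x <- .drop_na(values)
  if (length(x) < 3L) stop("need at least 3 finite values", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate input: sample has zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  stat_result("one_sample_t", statistic = tt$statistic, df = tt$parameter,
              p_value = tt$p.value,
              tails = if (alternative == "two.sided") "two" else "one",
              alpha_used = alpha, n_used = length(x),
              details = list(mean = mean(x)))
}

#' Mixed group-by-limb ANOVA (interaction test)
#'
#' Classical univariate mixed-design analysis of variance with one between-
#' participant factor (group) and one two-level within-participant factor
#' (limb), applied to the two per-limb activation columns.  With a two-level
#' within factor, sphericity holds trivially.  Returns the group-by-limb
#' interaction F with its degrees-of-freedom pair; main effects are kept in
#' `details`.
#'
#' @param cohort A cohort table (see [cohort_columns()]).
#' @param dv_cols Length-2 character vector naming the within-limb dependent
#'   columns, `c(intact, residual)`; default the two activation columns.
#' @param group_col Between-participant factor column (default `"group"`).
#' @param alpha Significance level for the interaction decision.
#' @return A [stat_result()] for the interaction.
#' @export
mixed_anova <- function(cohort, dv_cols = c("beta_intact_hand", "beta_residual_arm"),
                        group_col = "group", alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  stopifnot(length(dv_cols) == 2L, all(dv_cols %in% names(cohort)),
            group_col %in% names(cohort))
  miss <- !stats::complete.cases(cohort[dv_cols])
  if (any(miss)) {
    stop("missing within-participant values for: ",
         paste(cohort$participant_id[miss], collapse = ", "), call. = FALSE)
  }
  if (length(unique(cohort[[group_col]])) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n <- nrow(cohort)
  long <- data.frame(
    id = factor(rep(seq_len(n), times = 2L)),
    group = factor(rep(cohort[[group_col]], times = 2L)),
    limb = factor(rep(c("intact", "residual"), each = n)),
    value = c(cohort[[dv_cols[1L]]], cohort[[dv_cols[2L]]])
  )
  fit <- stats::aov(value ~ group * limb + Error(id), data = long)
  sm <- summary(fit)
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  between <- as.data.frame(sm[["Error: id"]][[1L]])
  rn <- trimws(rownames(within))
  ia <- which(rn == "group:limb"); res <- which(rn == "Residuals")
  out <- stat_result(
    "mixed_anova_interaction",
    statistic = within$`F value`[ia],
    df = c(within$Df[ia], within$Df[res]),
    p_value = within$`Pr(>F)`[ia],
    tails = "two", alpha_used = alpha, n_used = n,
    details = list(
      F_limb = within$`F value`[trimws(rownames(within)) == "limb"],
      p_limb = within$`Pr(>F)`[trimws(rownames(within)) == "limb"],
      F_group = between$`F value`[trimws(rownames(between)) == "group"],
      p_group = between$`Pr(>F)`[trimws(rownames(between)) == "group"]
    )
  )
  out
}

#' Covariate-adjusted group contrast (univariate GLM)
#'
#' Fits the linear model `dependent ~ group + covariates` and tests the group
#' effect by comparing against the covariates-only model, i.e. an F test with
#' 1 numerator degree of freedom.  With an empty covariate set this
#' reproduces the unadjusted one-way comparison exactly.  Participants with
#' missing values in any used column are excluded from this test only, and
#' the exclusions are recorded in `details`.
#'
#' @param cohort A cohort table.
#' @param dv Dependent column name.
#' @param group_col Two-level grouping column (rows with other levels should
#'   be filtered out beforehand).
#' @param covariates Character vector of numeric covariate columns (may be
#'   empty).
#' @param alpha Significance level.
#' @return A [stat_result()] with the group F and df `(1, n - k - 2)` where
#'   `k` is the number of covariates.
#' @export
covariate_adjusted_contrast <- function(cohort, dv, group_col = "group",
                                        covariates = character(), alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  used <- c(dv, group_col, covariates)
  stopifnot(all(used %in% names(cohort)))
  keep <- stats::complete.cases(cohort[used])
  excluded <- cohort$participant_id[!keep]
  dat <- cohort[keep, used, drop = FALSE]
  grp <- factor(dat[[group_col]])
  if (nlevels(grp) != 2L) {
    stop("group column must have exactly 2 levels after filtering (has ",
         nlevels(grp), ")", call. = FALSE)
  }
  if (length(covariates)) {
    X <- as.matrix(dat[covariates])
    if (!is.numeric(X)) stop("covariates must be numeric", call. = FALSE)
    nonconst <- X[, apply(X, 2L, function(v) stats::var(v) > 0), drop = FALSE]
    if (ncol(nonconst) && qr(cbind(1, nonconst))$rank < ncol(nonconst) + 1L) {
      stop("collinear covariates (rank deficiency) among: ",
           paste(covariates, collapse = ", "), call. = FALSE)
    }
  }
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- stats::lm(stats::reformulate(c(group_col, covariates), response = dv), data = dat)
  reduced <- stats::lm(stats::reformulate(rhs_cov, response = dv), data = dat)
  cmp <- stats::anova(reduced, full)
  Fval <- cmp$F[2L]
  pval <- cmp$`Pr(>F)`[2L]
  if (!is.finite(Fval)) {
    # perfect covariate fit: both models have ~zero residual SS; the group
    # adds nothing, so its contribution is a null effect, not a failure
    ss_gain <- cmp$`Sum of Sq`[2L]
    if (is.finite(ss_gain) && abs(ss_gain) <= 1e-10 * max(1, sum(dat[[dv]]^2))) {
      Fval <- 0; pval <- 1
    } else {
      stop("degenerate fit: non-finite group F", call. = FALSE)
    }
  }
  stat_result("covariate_adjusted_F",
              statistic = Fval, df = c(cmp$Df[2L], cmp$Res.Df[2L]),
              p_value = pval, tails = "two", alpha_used = alpha,
              n_used = nrow(dat),
              details = list(covariates = if (length(covariates)) covariates else "none",
                             excluded = if (length(excluded)) as.character(excluded) else "none"))
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values are
#'   dropped; n >= 3 required).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param alpha Significance level.
#' @return A [stat_result()] whose `statistic` is the correlation `r`, with
#'   `df = n - 2`; the t statistic is kept in `details`.
#' @export
pearson_corr <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         alpha = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  stat_result("pearson_r", statistic = ct$estimate, df = ct$parameter,
              p_value = ct$p.value,
              tails = if (alternative == "two.sided") "two" else "one",
              alpha_used = alpha, n_used = n,
              details = list(t = unname(ct$statistic)))
}

#' Partial correlation with nuisance covariates
#'
#' Correlation of the residuals of `x` and `y` after each is regressed (with
#' intercept) on the nuisance columns.  Used post hoc to exclude confounds
#' (amputation level, prosthesis usage, deprivation age, ...) from a
#' correlation.  Directional hypotheses must declare their tail; if
#' `alternative` is omitted the test falls back to two-tailed with a warning.
#'
#' @param x,y Numeric vectors.
#' @param nuisance Numeric vector, matrix or data frame of nuisance
#'   covariates (k columns); rows with any missing value are dropped.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.  `NULL`
#'   (default) warns and uses two-sided.
#' @param alpha Significance level.
#' @return A [stat_result()] whose `statistic` is the partial `r`, with
#'   `df = n - 2 - k`.
#' @export
partial_corr <- function(x, y, nuisance, alternative = NULL, alpha = 0.05) {
  if (is.null(alternative)) {
    warning("no one-tailed direction declared; using a two-tailed test",
            call. = FALSE)
    alternative <- "two.sided"
  }
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  Z <- as.matrix(as.data.frame(nuisance))
  storage.mode(Z) <- "double"
  stopifnot(length(x) == length(y), nrow(Z) == length(x))
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(Z), 1L, all)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n <= k + 2L) stop("need n > k + 2 complete rows", call. = FALSE)
  for (j in seq_len(k)) {
    if (isTRUE(all.equal(Z[, j], x)) || isTRUE(all.equal(Z[, j], y))) {
      stop("nuisance column ", j, " is identical to x or y", call. = FALSE)
    }
  }
  D <- cbind(1, Z)
  rx <- stats::lm.fit(D, x)$residuals
  ry <- stats::lm.fit(D, y)$residuals
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero residual variance after removing nuisance covariates", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tval), df),
    greater   = stats::pt(tval, df, lower.tail = FALSE),
    less      = stats::pt(tval, df)
  )
  stat_result("partial_r", statistic = r, df = df, p_value = p,
              tails = if (alternative == "two.sided") "two" else "one",
              alpha_used = alpha, n_used = n,
              details = list(t = tval, k = k, alternative = alternative))
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Two-tailed comparison of two independent correlation coefficients via the
#' variance-stabilising transform `atanh(r)`:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (each >= 4).
#' @param alpha Significance level.
#' @return A [stat_result()] with the z statistic and two-tailed normal p.
#' @export
fisher_compare <- function(r1, n1, r2, n2, alpha = 0.05) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 (the transform is undefined at 1)", call. = FALSE)
  }
  if (n1 < 4L || n2 < 4L) stop("each sample size must be >= 4", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat_result("fisher_r_to_z", statistic = z, df = NA_real_,
              p_value = 2 * stats::pnorm(-abs(z)), tails = "two",
              alpha_used = alpha, n_used = n1 + n2,
              details = list(r1 = r1, n1 = n1, r2 = r2, n2 = n2))
}

#' Run a list of planned and exploratory two-group contrasts
#'
#' Each contrast names a dependent column and two group levels and is run
#' through [gated_two_sample()].  Contrasts marked `planned = TRUE` are
#' tested at alpha = 0.025 (two pre-specified tests per limb); all others at
#' alpha = 0.05.  An optional `filter` expression (evaluated in the cohort's
#' columns) restricts the rows, e.g. to exclude above-elbow deprivation from
#' arm contrasts.
#'
#' @param cohort A cohort table.
#' @param plan A list of contrasts; each a list with elements `name`, `dv`
#'   (column), `groups` (length-2 character), optional `planned` (logical,
#'   default `FALSE`), optional `filter` (character, an expression over
#'   cohort columns), optional `group_col` (default `"group"`).
#' @return A named list of [stat_result()]s, one per contrast, in plan order.
#' @seealso [stat_results_table()] to flatten the list into a table.
#' @export
planned_comparisons <- function(cohort, plan) {
  cohort <- as.data.frame(cohort)
  out <- list()
  for (ct in plan) {
    stopifnot(!is.null(ct$name), !is.null(ct$dv), length(ct$groups) == 2L)
    group_col <- if (is.null(ct$group_col)) "group" else ct$group_col
    if (!ct$dv %in% names(cohort)) {
      stop("contrast '", ct$name, "': unknown column '", ct$dv, "'", call. = FALSE)
    }
    unknown <- setdiff(ct$groups, unique(as.character(cohort[[group_col]])))
    if (length(unknown)) {
      stop("contrast '", ct$name, "': unknown group '", unknown[1L], "'",
           call. = FALSE)
    }
    dat <- cohort
    if (!is.null(ct$filter)) {
      keep <- eval(parse(text = ct$filter), envir = dat, enclos = baseenv())
      dat <- dat[keep & !is.na(keep), , drop = FALSE]
    }
    planned <- isTRUE(ct$planned)
    a <- dat[[ct$dv]][dat[[group_col]] == ct$groups[1L]]
    b <- dat[[ct$dv]][dat[[group_col]] == ct$groups[2L]]
    res <- gated_two_sample(a, b, alpha = if (planned) 0.025 else 0.05)
    res$details$planned <- planned
    res$details$groups <- ct$groups
    out[[ct$name]] <- res
  }
  out
}
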