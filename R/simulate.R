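#' Evaluate code under a local, explicit random seed
#'
#' Both generators draw from one pseudo-random stream seeded explicitly per
#' call; the caller's global RNG state is saved and restored, so simulation
#' never leaks into, or depends on, ambient random state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the paired accelerometer-trace generator
#'
#' Defines the simulated recording conditions: burst-like movement events on
#' a noisy, gravity-offset baseline, with whole-body co-movements shared
#' between the two limbs.
#'
#' @param duration_s Trace length in seconds (default 600).
#' @param rate_intact,rate_residual Limb-specific movement events per minute
#'   (defaults 6 and 2: intact-hand dominance, as observed in one-handed
#'   cohorts).
#' @param burst_amp Peak-to-peak burst amplitude in m/s^2 (default 0.5).
#' @param burst_dur_ms Burst duration in ms (default 1000, a typical reach;
#'   long enough that a 500 ms boxcar smoother attenuates but does not
#'   cancel the single-cycle waveform).
#' @param coupled_rate Whole-body events per minute appearing on both limbs
#'   (default 1).
#' @param noise_sd Sensor noise standard deviation in m/s^2 (default 0.02).
#' @param gravity_offset Per-axis constant offset in m/s^2 (default
#'   `c(0, 0, 9.81)`); detection is offset-invariant, so this only exercises
#'   that invariance.
#' @param min_gap_ms Minimum gap between consecutive event intervals in ms
#'   (default 2000).  Keeps events identifiable: the gap must exceed the
#'   smoothing spread plus the quiescence and window spans (500 + 400 + 400
#'   ms at the detector defaults) for neighbouring events to remain
#'   separable; candidate events closer than this are discarded at draw
#'   time and never enter the ground truth.
#' @param sample_rate Samples per second (default 100).
#' @param seed Integer random seed (default 1).
#' @return An object of class `accel_sim_params`.
#' @export
accel_sim_params <- function(duration_s = 600, rate_intact = 6, rate_residual = 2,
                             burst_amp = 0.5, burst_dur_ms = 1000,
                             coupled_rate = 1, noise_sd = 0.02,
                             gravity_offset = c(0, 0, 9.81),
                             min_gap_ms = 2000, sample_rate = 100, seed = 1L) {
  stopifnot(duration_s > 0, rate_intact >= 0, rate_residual >= 0,
            coupled_rate >= 0, burst_amp > 0, burst_dur_ms > 0,
            noise_sd >= 0, min_gap_ms >= 0, sample_rate > 0,
            length(gravity_offset) == 3L)
  max_rate <- max(rate_intact, rate_residual) + coupled_rate
  if (max_rate > 0 && 60 / max_rate < 5 * burst_dur_ms / 1000) {
    warning("expected event spacing is not much larger than the burst ",
            "duration; events may be hard to separate", call. = FALSE)
  }
  structure(list(duration_s = duration_s, rate_intact = rate_intact,
                 rate_residual = rate_residual, burst_amp = burst_amp,
                 burst_dur_ms = burst_dur_ms, coupled_rate = coupled_rate,
                 noise_sd = noise_sd, gravity_offset = gravity_offset,
                 min_gap_ms = min_gap_ms, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "accel_sim_params")
}

# Draw event onset times for one Poisson process, keeping only candidates
# whose interval stays min_gap away from every interval already kept.
.draw_onsets <- function(rate_per_min, duration_s, burst_s, min_gap_s, margin_s,
                         fixed = numeric(0)) {
  lo <- margin_s
  hi <- duration_s - margin_s - burst_s
  if (hi <= lo) return(numeric(0))
  n <- stats::rpois(1L, rate_per_min * duration_s / 60)
  cand <- sort(stats::runif(n, lo, hi))
  kept <- numeric(0)
  for (t in cand) {
    others <- c(fixed, kept)
    if (!length(others) || all(abs(t - others) >= burst_s + min_gap_s)) {
      kept <- c(kept, t)
    }
  }
  kept
}

#' Generate a pair of accelerometer traces with ground truth
#'
#' Each limb's trace is a per-axis gravity offset plus Gaussian sensor noise
#' plus movement bursts: limb-specific bursts arrive as a Poisson process at
#' that limb's rate, and whole-body (coupled) bursts at `coupled_rate` share
#' their timing across limbs but draw their movement axis independently per
#' limb (a trunk movement registers on both monitors, generally on different
#' axes).  A burst is a single-cycle sinusoid of peak-to-peak amplitude
#' `burst_amp` on one randomly chosen axis.  The returned ground truth lists
#' every burst interval per limb; identical parameters and seed give
#' bit-identical output.
#'
#' @param params An [accel_sim_params()].
#' @return A list with elements `intact` and `residual` (each an
#'   [accel_trace()]) and `truth`: a list with `events_intact` and
#'   `events_residual` (tibbles: `start_s`, `end_s`, `axis`, `coupled`) and
#'   the generating `params`.
#' @export
generate_paired_accel <- function(params = accel_sim_params()) {
  stopifnot(inherits(params, "accel_sim_params"))
  with_seed(params$seed, {
    sr <- params$sample_rate
    n <- as.integer(round(params$duration_s * sr))
    burst_s <- params$burst_dur_ms / 1000
    gap_s <- params$min_gap_ms / 1000
    margin_s <- gap_s + burst_s

    coupled <- .draw_onsets(params$coupled_rate, params$duration_s, burst_s,
                            gap_s, margin_s)
    own <- list(
      intact = .draw_onsets(params$rate_intact, params$duration_s, burst_s,
                            gap_s, margin_s, fixed = coupled),
      residual = .draw_onsets(params$rate_residual, params$duration_s, burst_s,
                              gap_s, margin_s, fixed = coupled)
    )

    dur_smp <- max(2L, as.integer(round(burst_s * sr)))
    wave <- (params$burst_amp / 2) * sin(2 * pi * seq(0, 1, length.out = dur_smp))

    make_limb <- function(limb) {
      ax <- matrix(stats::rnorm(n * 3L, sd = params$noise_sd), ncol = 3L)
      ax <- sweep(ax, 2L, params$gravity_offset, "+")
      onsets <- sort(c(coupled, own[[limb]]))
      is_coupled <- onsets %in% coupled
      axis_pick <- if (length(onsets)) sample.int(3L, length(onsets), replace = TRUE) else integer(0)
      for (i in seq_along(onsets)) {
        s0 <- as.integer(round(onsets[i] * sr)) + 1L
        idx <- s0:(s0 + dur_smp - 1L)
        ax[idx, axis_pick[i]] <- ax[idx, axis_pick[i]] + wave
      }
      list(
        trace = accel_trace(ax[, 1L], ax[, 2L], ax[, 3L], sr, limb),
        events = tibble::tibble(
          start_s = onsets, end_s = onsets + burst_s,
          axis = c("x", "y", "z")[axis_pick], coupled = is_coupled
        )
      )
    }
    li <- make_limb("intact")
    lr <- make_limb("residual")
    list(intact = li$trace, residual = lr$trace,
         truth = list(events_intact = li$events, events_residual = lr$events,
                      params = params))
  })
}

#' Parameters for the synthetic cohort generator
#'
#' Defines the statistical structure the cohort analysis assumes: group
#' sizes matching the study design (11 congenital, 18 acquired one-handed
#' participants, 22 two-handed controls), group-specific laterality-index and
#' questionnaire distributions with the acquired group favouring the intact
#' hand and the congenital group reporting more residual-arm use, a
#' group-by-limb activation pattern in which each group's over-used limb is
#' over-represented, and generating correlations linking residual-arm usage
#' to intact-hand activation and phantom pain to usage.
#'
#' Defaults are chosen to mirror the direction and approximate effect
#' magnitudes of the cohort the pipeline targets; score distributions are
#' kept at least ~2.3 standard deviations inside their bounds so that fewer
#' than 1% of draws are clipped.
#'
#' @param n_congenital,n_acquired,n_control Group sizes (each >= 2).
#' @param li_mean,li_sd Named (`congenital`, `acquired`) means and standard
#'   deviations of the laterality index; controls have none.
#' @param mal_mean,mal_sd Means (named per one-handed group) and common
#'   standard deviation of the Motor Activity Log score.
#' @param beta_cell_means 3-by-2 matrix of activation means, rows
#'   `congenital`, `acquired`, `control`, columns `intact`, `residual`.
#' @param beta_sd Activation noise standard deviation.
#' @param usage_beta_rho Generating correlation between the usage (MAL)
#'   latent and intact-hand activation, within group (default -0.43: more
#'   residual-arm use, less intact-hand activation in the deprived cortex).
#' @param pain_usage_rho Generating correlation between the chronic-pain
#'   latent and usage (default -0.40: worse chronic pain, less residual-arm
#'   use).
#' @param seed Integer random seed (default 1).
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_congenital = 11, n_acquired = 18, n_control = 22,
                              li_mean = c(congenital = 0.30, acquired = 0.60),
                              li_sd = c(congenital = 0.20, acquired = 0.17),
                              mal_mean = c(congenital = 0.55, acquired = 0.35),
                              mal_sd = 0.15,
                              beta_cell_means = matrix(
                                c(0.4, 1.2, 0.5, 1.2, 0.3, 0.5), nrow = 3L,
                                dimnames = list(c("congenital", "acquired", "control"),
                                                c("intact", "residual"))),
                              beta_sd = 0.7,
                              usage_beta_rho = -0.43,
                              pain_usage_rho = -0.40,
                              seed = 1L) {
  stopifnot(n_congenital >= 2, n_acquired >= 2, n_control >= 2,
            all(li_sd >= 0), all(mal_sd >= 0), beta_sd >= 0,
            all(c("congenital", "acquired") %in% names(li_mean)),
            all(c("congenital", "acquired") %in% names(li_sd)),
            all(c("congenital", "acquired") %in% names(mal_mean)),
            identical(dim(beta_cell_means), c(3L, 2L)))
  if (abs(usage_beta_rho) >= 1 || abs(pain_usage_rho) >= 1) {
    stop("generating correlations must satisfy |rho| < 1", call. = FALSE)
  }
  structure(list(n_congenital = n_congenital, n_acquired = n_acquired,
                 n_control = n_control, li_mean = li_mean, li_sd = li_sd,
                 mal_mean = mal_mean, mal_sd = mal_sd,
                 beta_cell_means = beta_cell_means, beta_sd = beta_sd,
                 usage_beta_rho = usage_beta_rho,
                 pain_usage_rho = pain_usage_rho, seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Null-regime cohort parameters
#'
#' A convenience constructor for calibration studies: all group means equal
#' and all generating correlations zero, so every test's nominal rejection
#' rate can be checked against its alpha.
#'
#' @param seed Integer random seed.
#' @param ... Overrides passed on to [cohort_sim_params()].
#' @return A `cohort_sim_params` object with no true effects.
#' @export
null_cohort_params <- function(seed = 1L, ...) {
  cohort_sim_params(
    li_mean = c(congenital = 0.45, acquired = 0.45),
    li_sd = c(congenital = 0.17, acquired = 0.17),
    mal_mean = c(congenital = 0.45, acquired = 0.45),
    beta_cell_means = matrix(0.6, nrow = 3L, ncol = 2L,
                             dimnames = list(c("congenital", "acquired", "control"),
                                             c("intact", "residual"))),
    usage_beta_rho = 0, pain_usage_rho = 0, seed = seed, ...)
}

.clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a synthetic cohort
#'
#' Draws per-group laterality indices, Motor Activity Log scores, phantom
#' pain ratings, covariates and group-by-limb activation values.  The usage
#' latent and intact-hand activation, and the pain latent and usage, are
#' drawn from bivariate normal structures with the generating correlations in
#' the parameters (within group; pooled-sample correlations additionally
#' reflect the group mean differences).  Bounded scores are clipped to their
#' ranges; any clipping is reported via a message and recorded in the
#' `clipped` attribute.  Controls carry activation values only; their
#' amputation fields, questionnaire, pain and laterality entries are missing.
#'
#' @param params A [cohort_sim_params()].
#' @return A validated cohort [tibble::tibble()] (see [cohort_columns()]),
#'   with attribute `clipped` (number of clipped score draws).
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed(params$seed, {
    bm <- params$beta_cell_means
    rho_ub <- params$usage_beta_rho
    rho_pu <- params$pain_usage_rho
    n_clip <- 0L

    one_handed <- function(group, n, prefix, amp_prob) {
      u <- stats::rnorm(n)                       # usage latent
      mal_raw <- params$mal_mean[[group]] + params$mal_sd * u
      mal <- .clip(mal_raw, 0, 1)
      li_raw <- params$li_mean[[group]] + params$li_sd[[group]] * stats::rnorm(n)
      li <- .clip(li_raw, -1, 1)
      n_clip <<- n_clip + sum(mal != mal_raw) + sum(li != li_raw)
      beta_intact <- bm[group, "intact"] +
        params$beta_sd * (rho_ub * u + sqrt(1 - rho_ub^2) * stats::rnorm(n))
      beta_residual <- bm[group, "residual"] + params$beta_sd * stats::rnorm(n)
      pain_z <- rho_pu * u + sqrt(1 - rho_pu^2) * stats::rnorm(n)
      depriv_age <- if (group == "congenital") rep(0, n) else
        round(stats::runif(n, 11, 48))
      tibble::tibble(
        participant_id = sprintf("%s%02d", prefix, seq_len(n)),
        group = group,
        amputation_level = sample(1:5, n, replace = TRUE, prob = amp_prob),
        side = sample(c("L", "R"), n, replace = TRUE),
        deprivation_age = depriv_age,
        cosmetic_prosthesis_usage = sample(0:5, n, replace = TRUE,
                                           prob = c(.35, .15, .15, .1, .15, .1)),
        functional_prosthesis_usage = sample(0:5, n, replace = TRUE,
                                             prob = c(.3, .2, .15, .1, .15, .1)),
        mal_score = mal,
        pain_intensity = .clip(round(4 + 2.2 * pain_z), 0, 10),
        pain_frequency = .clip(round(3 - 1.2 * pain_z), 1, 5),
        laterality_index = li,
        beta_intact_hand = beta_intact,
        beta_residual_arm = beta_residual
      )
    }

    cong <- one_handed("congenital", params$n_congenital, "C",
                       amp_prob = c(0, .05, 0, .75, .2))
    acq <- one_handed("acquired", params$n_acquired, "A",
                      amp_prob = c(.05, .35, .05, .4, .15))
    nc <- params$n_control
    ctrl <- tibble::tibble(
      participant_id = sprintf("N%02d", seq_len(nc)),
      group = "control",
      amputation_level = NA_real_, side = NA_character_,
      deprivation_age = NA_real_,
      cosmetic_prosthesis_usage = NA_real_,
      functional_prosthesis_usage = NA_real_,
      mal_score = NA_real_, pain_intensity = NA_real_,
      pain_frequency = NA_real_, laterality_index = NA_real_,
      beta_intact_hand = bm["control", "intact"] + params$beta_sd * stats::rnorm(nc),
      beta_residual_arm = bm["control", "residual"] + params$beta_sd * stats::rnorm(nc)
    )
    out <- validate_cohort(rbind(cong, acq, ctrl))
    if (n_clip > 0L) {
      message("generate_cohort: ", n_clip, " bounded score draw(s) clipped to range")
    }
    attr(out, "clipped") <- n_clip
    out
  })
}
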