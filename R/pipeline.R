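#' Build a recording manifest from a directory
#'
#' Scans a directory for accelerometer files named
#' `<participant>_<limb>[_<anything>].csv` (limb one of `intact`,
#' `residual`).  Several files per participant and limb (e.g. recording
#' days) are allowed; the pipeline pools their counts, so both limbs must
#' pool the same epochs for the laterality ratio to cancel recording-time
#' differences.
#'
#' @param dir Directory to scan.
#' @return A [tibble::tibble()] with columns `participant_id`, `limb`,
#'   `path`, one row per file.
#' @export
accel_manifest <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  m <- regmatches(basename(files),
                  regexec("^(.+?)_(intact|residual)(_[^.]*)?\\.csv$", basename(files)))
  keep <- lengths(m) == 4L
  tibble::tibble(
    participant_id = vapply(m[keep], `[`, "", 2L),
    limb = vapply(m[keep], `[`, "", 3L),
    path = files[keep]
  )
}

#' Run the accelerometry usage pipeline
#'
#' For each participant with at least one recording per limb: read every
#' file, run the detection chain (smoothing, sliding-window ranges,
#' threshold-and-quiescence event detection), pool movement counts per limb
#' across files, and compute the movement laterality index.  Participants
#' missing a limb's recording are skipped with a logged reason.
#'
#' @param manifest A data frame with columns `participant_id`, `limb`
#'   (`intact`/`residual`) and `path`, e.g. from [accel_manifest()].
#' @param params A [detector_params()].
#' @param sample_rate Declared sample rate of the recordings (Hz).
#' @param out_dir Optional directory: if given, writes `usage.csv`,
#'   `events.csv` and `run_log.txt` (the effective parameter set and any
#'   skips) there.
#' @return A list: `usage` (tibble: participant, pooled per-limb counts,
#'   wear times in s, laterality index), `events` (tibble of per-participant
#'   event annotations: limb, start_s, end_s, triggering axes) and `skipped`
#'   (named character vector of reasons).
#' @export
run_usage_pipeline <- function(manifest, params = detector_params(),
                               sample_rate = 100, out_dir = NULL) {
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("participant_id", "limb", "path") %in% names(manifest)))
  usage_rows <- list()
  event_rows <- list()
  skipped <- character(0)

  for (pid in unique(manifest$participant_id)) {
    sub <- manifest[manifest$participant_id == pid, , drop = FALSE]
    have <- unique(sub$limb)
    if (!all(c("intact", "residual") %in% have)) {
      skipped[pid] <- paste("missing", setdiff(c("intact", "residual"), have)[1L],
                            "recording")
      next
    }
    counts <- c(intact = 0L, residual = 0L)
    wear <- c(intact = 0, residual = 0)
    for (i in seq_len(nrow(sub))) {
      limb <- sub$limb[i]
      tr <- read_accel(sub$path[i], limb_label = limb, sample_rate = sample_rate)
      ev <- detect_movements(smooth_trace(tr, params), params)
      counts[limb] <- counts[limb] + nrow(ev)
      wear[limb] <- wear[limb] + tr$wear_duration
      if (nrow(ev)) {
        event_rows[[length(event_rows) + 1L]] <- tibble::tibble(
          participant_id = pid, limb = limb, file = basename(sub$path[i]),
          start_s = ev$start_s, end_s = ev$end_s,
          triggering_axes = ev$triggering_axes
        )
      }
    }
    row <- usage_record(pid, counts["intact"], counts["residual"])
    row$wear_s_intact <- wear[["intact"]]
    row$wear_s_residual <- wear[["residual"]]
    usage_rows[[pid]] <- row
  }

  usage <- if (length(usage_rows)) do.call(rbind, usage_rows) else
    tibble::tibble(participant_id = character(0), n_intact = integer(0),
                   n_residual = integer(0), laterality_index = numeric(0),
                   wear_s_intact = numeric(0), wear_s_residual = numeric(0))
  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    tibble::tibble(participant_id = character(0), limb = character(0),
                   file = character(0), start_s = numeric(0),
                   end_s = numeric(0), triggering_axes = character(0))
  if (!nrow(usage)) warning("no participant had recordings for both limbs",
                            call. = FALSE)
  for (pid in names(skipped)) {
    message("skipping participant '", pid, "': ", skipped[pid])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(usage, file.path(out_dir, "usage.csv"), row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("detector: smooth_ms=%g window_ms=%g threshold=%g quiescence_ms=%g",
              params$smooth_ms, params$window_ms, params$threshold,
              params$quiescence_ms),
      sprintf("sample_rate: %g", sample_rate),
      sprintf("participants: %d analysed, %d skipped", nrow(usage), length(skipped)),
      if (length(skipped)) paste0("skipped ", names(skipped), ": ", skipped) else character(0)
    ), file.path(out_dir, "run_log.txt"))
  }
  list(usage = usage, events = events, skipped = skipped)
}

#' Read an analysis plan from a YAML file
#'
#' The plan is a YAML list of analysis steps executed in order by
#' [run_cohort_analysis()].  Each step has a `name`, a `type` (one of
#' `two_sample`, `one_sample`, `mixed_anova`, `covariate_contrast`,
#' `pearson`, `partial`, `fisher`) and type-specific fields; see the
#' template in `inst/extdata/analysis_plan.yaml`.  Per-analysis exclusion
#' rules (e.g. excluding above-elbow deprivation from arm contrasts) are
#' expressed as declarative `filter` expressions over cohort columns, not
#' hard-coded.
#'
#' @param path Path to the YAML plan.
#' @return The plan as a list of steps.
#' @export
read_analysis_plan <- function(path) {
  plan <- yaml::read_yaml(path)
  stopifnot(is.list(plan), length(plan) > 0L)
  lapply(plan, function(step) {
    # YAML 1.1 reads a bare `y:` key as boolean TRUE; map it back
    names(step)[names(step) %in% c("TRUE", "yes")] <- "y"
    step
  })
}

.apply_filter <- function(cohort, filter) {
  if (is.null(filter)) return(cohort)
  keep <- eval(parse(text = filter), envir = cohort, enclos = baseenv())
  cohort[keep & !is.na(keep), , drop = FALSE]
}

.group_values <- function(cohort, col, group, group_col = "group") {
  cohort[[col]][cohort[[group_col]] == group]
}

#' Execute a cohort analysis plan
#'
#' Runs the configured analysis steps in order over a validated cohort
#' table.  A step that fails (e.g. an all-missing column) is logged as a
#' failure and the run continues.  `fisher` steps may reference the results
#' of two earlier correlation steps by name (`ref1`, `ref2`) instead of
#' passing `r`/`n` directly.
#'
#' @param cohort A validated cohort table (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param plan A plan list, e.g. from [read_analysis_plan()].
#' @param out_dir Optional directory: if given, writes `stat_results.csv`
#'   and `analysis_log.txt` there.
#' @return A list: `results` (named list of [stat_result()]s),
#'   `table` (their [stat_results_table()]) and `failures` (named character
#'   vector of error messages for failed steps).
#' @export
run_cohort_analysis <- function(cohort, plan, out_dir = NULL) {
  cohort <- validate_cohort(cohort)
  results <- list()
  failures <- character(0)

  for (step in plan) {
    stopifnot(!is.null(step$name), !is.null(step$type))
    res <- tryCatch({
      dat <- .apply_filter(cohort, step$filter)
      switch(step$type,
        two_sample = {
          r <- planned_comparisons(dat, list(step))[[step$name]]
          r
        },
        one_sample = {
          v <- .group_values(dat, step$dv, step$group)
          one_sample_vs_zero(v, alternative = step$alternative %||% "two.sided",
                             alpha = step$alpha %||% 0.05)
        },
        mixed_anova = mixed_anova(
          dat, dv_cols = unlist(step$dv_cols %||%
                                  c("beta_intact_hand", "beta_residual_arm")),
          alpha = step$alpha %||% 0.05),
        covariate_contrast = {
          d2 <- dat[dat$group %in% unlist(step$groups), , drop = FALSE]
          covariate_adjusted_contrast(d2, dv = step$dv,
                                      covariates = unlist(step$covariates %||% character(0)),
                                      alpha = step$alpha %||% 0.05)
        },
        pearson = pearson_corr(dat[[step$x]], dat[[step$y]],
                               alternative = step$alternative %||% "two.sided",
                               alpha = step$alpha %||% 0.05),
        partial = partial_corr(dat[[step$x]], dat[[step$y]],
                               nuisance = dat[unlist(step$nuisance)],
                               alternative = step$alternative,
                               alpha = step$alpha %||% 0.05),
        fisher = {
          if (!is.null(step$ref1)) {
            r1 <- results[[step$ref1]]; r2 <- results[[step$ref2]]
            if (is.null(r1) || is.null(r2)) stop("fisher step references unknown results")
            fisher_compare(r1$statistic, r1$n_used, r2$statistic, r2$n_used,
                           alpha = step$alpha %||% 0.05)
          } else {
            fisher_compare(step$r1, step$n1, step$r2, step$n2,
                           alpha = step$alpha %||% 0.05)
          }
        },
        stop("unknown step type '", step$type, "'")
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[step$name] <- conditionMessage(res)
      message("analysis step '", step$name, "' failed: ", conditionMessage(res))
    } else {
      results[[step$name]] <- res
    }
  }

  tab <- stat_results_table(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "stat_results.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("steps run: %d; failed: %d", length(results), length(failures)),
      if (length(failures)) paste0("failed ", names(failures), ": ", failures) else character(0)
    ), file.path(out_dir, "analysis_log.txt"))
  }
  list(results = results, table = tab, failures = failures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
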