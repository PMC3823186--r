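#' Construct a tri-axial acceleration trace
#'
#' An `accel_trace` holds one limb's raw (or smoothed) tri-axial acceleration
#' time series in m/s^2, together with its sample rate and limb label.
#' Acceleration is stored *including* the gravity component: the movement
#' detector works on within-window ranges, which cancel any constant offset,
#' so no gravity removal is performed anywhere in the pipeline.
#'
#' Sample spacing is assumed uniform at the declared rate; a time column in an
#' input file is treated as informative only.
#'
#' @param ax,ay,az Numeric vectors of equal length (acceleration in m/s^2).
#' @param sample_rate Samples per second (Hz); the study devices record at 100.
#' @param limb_label One of `"intact"` or `"residual"`.
#' @return An object of class `accel_trace`: a list with elements `axes`
#'   (an n-by-3 numeric matrix with columns `x`, `y`, `z`), `sample_rate`,
#'   `limb_label` and `wear_duration` (seconds, `n / sample_rate`).
#' @examples
#' tr <- accel_trace(rnorm(200), rnorm(200), rnorm(200) + 9.81, 100, "intact")
#' tr$wear_duration
#' @export
accel_trace <- function(ax, ay, az, sample_rate, limb_label = c("intact", "residual")) {
  limb_label <- match.arg(limb_label)
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n) {
    stop("all three axis vectors must have identical length >= 1", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || !is.finite(sample_rate) ||
      sample_rate <= 0) {
    stop("sample_rate must be a single positive number (Hz)", call. = FALSE)
  }
  axes <- cbind(x = as.numeric(ax), y = as.numeric(ay), z = as.numeric(az))
  if (!all(is.finite(axes))) {
    bad <- which(!apply(is.finite(axes), 1L, all))[1L]
    stop("non-finite acceleration sample at row ", bad, call. = FALSE)
  }
  structure(
    list(axes = axes, sample_rate = sample_rate, limb_label = limb_label,
         wear_duration = n / sample_rate),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %s limb: %d samples at %g Hz (%.1f s)\n",
              x$limb_label, nrow(x$axes), x$sample_rate, x$wear_duration))
  invisible(x)
}

#' Number of samples in a trace
#' @param trace An [accel_trace()].
#' @return Integer sample count.
#' @export
n_samples <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  nrow(trace$axes)
}

#' Read a raw accelerometer recording
#'
#' Reads a comma-delimited text file with one header row and four columns:
#' a time stamp (seconds; informative only) and three acceleration axes in
#' m/s^2.  Both the long header (`time_s, ax_ms2, ay_ms2, az_ms2`) and the
#' short one (`time, ax, ay, az`) are accepted.
#'
#' @param path Path to the delimited file.
#' @param limb_label `"intact"` or `"residual"`.
#' @param sample_rate Declared sample rate in Hz (default 100, the study
#'   devices' rate).  The time column is not used to infer it.
#' @return A validated [accel_trace()].
#' @seealso [write_accel()]
#' @export
read_accel <- function(path, limb_label = c("intact", "residual"), sample_rate = 100) {
  limb_label <- match.arg(limb_label)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  header_long  <- c("time_s", "ax_ms2", "ay_ms2", "az_ms2")
  header_short <- c("time", "ax", "ay", "az")
  if (identical(names(raw), header_long) || identical(names(raw), header_short)) {
    names(raw) <- header_short
  } else {
    stop("'", path, "': expected columns ", paste(header_long, collapse = ", "),
         " (or ", paste(header_short, collapse = ", "), "), found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) < 1L) stop("'", path, "': no data rows", call. = FALSE)
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (col in names(num)) {
    bad <- which(is.na(num[[col]]) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop("'", path, "': non-numeric value '", raw[[col]][bad[1L]],
           "' in column '", col, "', row ", bad[1L], call. = FALSE)
    }
    if (anyNA(num[[col]])) {
      stop("'", path, "': missing value in column '", col, "', row ",
           which(is.na(num[[col]]))[1L], call. = FALSE)
    }
  }
  accel_trace(num$ax, num$ay, num$az, sample_rate = sample_rate,
              limb_label = limb_label)
}

#' Write an accelerometer recording
#'
#' Writes the comma-delimited format that [read_accel()] reads (header
#' `time_s, ax_ms2, ay_ms2, az_ms2`).  Full double precision is kept so that
#' a write/read round trip reproduces the samples exactly.
#'
#' @param trace An [accel_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accel <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- nrow(trace$axes)
  df <- data.frame(
    time_s = format((seq_len(n) - 1L) / trace$sample_rate, digits = 10),
    ax_ms2 = format(trace$axes[, "x"], digits = 17),
    ay_ms2 = format(trace$axes[, "y"], digits = 17),
    az_ms2 = format(trace$axes[, "z"], digits = 17)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- cohort table -----------------------------------------------------------

#' Cohort table column schema
#'
#' The canonical column set for a cohort table, one row per participant:
#' \describe{
#'   \item{participant_id}{opaque label, unique}
#'   \item{group}{`congenital`, `acquired` or `control`}
#'   \item{amputation_level}{integer 1--5 (1 = through shoulder, 2 = above
#'     elbow, 3 = through elbow, 4 = below elbow, 5 = through wrist);
#'     missing allowed only for controls}
#'   \item{side}{`L` or `R`; missing allowed only for controls}
#'   \item{deprivation_age}{years (0 for congenital absence); missing allowed
#'     only for controls}
#'   \item{cosmetic_prosthesis_usage, functional_prosthesis_usage}{frequency
#'     codes 0--5 (0 = never ... 5 = more than 8 hr a day)}
#'   \item{mal_score}{modified Motor Activity Log score in \[0, 1\]}
#'   \item{pain_intensity}{0--10 rating}
#'   \item{pain_frequency}{code 1--5 (1 = all the time ... 5 = once or less
#'     per month)}
#'   \item{laterality_index}{movement laterality index in \[-1, 1\]}
#'   \item{beta_intact_hand, beta_residual_arm}{externally supplied region-of-
#'     interest activation estimates (arbitrary units); for controls these are
#'     the dominant-hand / nondominant-arm values}
#' }
#' @return Character vector of the column names, in order.
#' @export
cohort_columns <- function() {
  c("participant_id", "group", "amputation_level", "side", "deprivation_age",
    "cosmetic_prosthesis_usage", "functional_prosthesis_usage", "mal_score",
    "pain_intensity", "pain_frequency", "laterality_index",
    "beta_intact_hand", "beta_residual_arm")
}

.cohort_groups <- c("congenital", "acquired", "control")

#' Validate a cohort table
#'
#' Checks every row against the coded ranges documented in
#' [cohort_columns()].  Missing values are `NA` (empty cells on disk), never
#' sentinel numbers.  `amputation_level`, `side` and `deprivation_age` may be
#' missing only for controls; any other out-of-range or missing-where-required
#' value raises an error naming the participant and the field.
#'
#' @param cohort A data frame with the [cohort_columns()] schema.
#' @return The validated cohort as a [tibble::tibble()].
#' @export
validate_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(cohort), cohort_columns())
  cohort <- cohort[c(cohort_columns(), extra)]   # extra (derived) columns ride along
  ids <- as.character(cohort$participant_id)
  if (anyNA(ids) || any(ids == "")) stop("participant_id must be non-missing", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicated participant_id: ", ids[anyDuplicated(ids)], call. = FALSE)
  }

  fail <- function(i, field, why) {
    stop("participant '", ids[i], "', field '", field, "': ", why, call. = FALSE)
  }
  check_range <- function(field, lo, hi, integer = FALSE) {
    v <- cohort[[field]]
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      if (!is.finite(v[i]) || v[i] < lo || v[i] > hi) {
        fail(i, field, paste0("value ", v[i], " outside [", lo, ", ", hi, "]"))
      }
      if (integer && v[i] != round(v[i])) fail(i, field, "must be an integer code")
    }
  }

  grp <- as.character(cohort$group)
  for (i in seq_along(grp)) {
    if (is.na(grp[i]) || !grp[i] %in% .cohort_groups) {
      fail(i, "group", paste0("'", grp[i], "' is not one of ",
                              paste(.cohort_groups, collapse = "/")))
    }
  }
  sides <- as.character(cohort$side)
  for (i in seq_along(sides)) {
    if (!is.na(sides[i]) && !sides[i] %in% c("L", "R")) {
      fail(i, "side", paste0("'", sides[i], "' is not L or R"))
    }
  }
  check_range("amputation_level", 1, 5, integer = TRUE)
  check_range("deprivation_age", 0, 150)
  check_range("cosmetic_prosthesis_usage", 0, 5, integer = TRUE)
  check_range("functional_prosthesis_usage", 0, 5, integer = TRUE)
  check_range("mal_score", 0, 1)
  check_range("pain_intensity", 0, 10)
  check_range("pain_frequency", 1, 5, integer = TRUE)
  check_range("laterality_index", -1, 1)

  # fields that only controls may leave blank
  for (field in c("amputation_level", "deprivation_age", "side")) {
    bad <- which(is.na(cohort[[field]]) & grp != "control")
    if (length(bad)) fail(bad[1L], field, "missing (allowed only for controls)")
  }
  tibble::as_tibble(cohort)
}

#' Read a cohort table
#'
#' Reads a comma-delimited cohort table (schema in [cohort_columns()]; a
#' template ships in `inst/extdata/cohort_template.csv`) and validates every
#' row.  Empty cells become `NA` and are preserved as missing, never coerced
#' to zero.
#'
#' @param path Path to the delimited file.
#' @return A validated [tibble::tibble()] of participant records.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("'", path, "': missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns(), c("participant_id", "group", "side"))
  out <- raw[c(cohort_columns(), setdiff(names(raw), cohort_columns()))]
  out[out == ""] <- NA
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad)) {
      stop("'", path, "': non-numeric value '", out[[col]][bad[1L]],
           "' in column '", col, "', row ", bad[1L], call. = FALSE)
    }
    out[[col]] <- v
  }
  # extra (derived) columns ride along; convert them when fully numeric
  for (col in setdiff(names(out), cohort_columns())) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (!any(is.na(v) & !is.na(out[[col]]))) out[[col]] <- v
  }
  validate_cohort(out)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: missing values are written as empty cells.
#'
#' @param cohort A validated cohort table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  df <- as.data.frame(cohort)
  num_cols <- setdiff(cohort_columns(), c("participant_id", "group", "side"))
  for (col in num_cols) df[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  df[df == "NA"] <- ""
  df[is.na(df)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
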