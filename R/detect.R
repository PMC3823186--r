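#' Movement-detector parameters
#'
#' Parameters of the accelerometry processing chain: boxcar smoothing,
#' sliding-window range computation, and threshold-with-quiescence event
#' detection.
#'
#' @param smooth_ms Smoothing kernel duration in ms (default 500).  The kernel
#'   is a centred boxcar (moving average), the simplest reading of smoothing
#'   that discards high-frequency noise.
#' @param window_ms Sliding-window duration in ms (default 400).  The window
#'   slides with a stride of one sample; within each window the max-minus-min
#'   acceleration range is computed per axis.
#' @param threshold Acceleration-range threshold in m/s^2 (default 0.2).  A
#'   window is "moving" when its range exceeds the threshold on at least one
#'   axis, and "still" when its range is below the threshold on all axes.
#' @param quiescence_ms Required still period immediately before and after an
#'   event, in ms (default 400, i.e. one full window on each side).  The
#'   required duration of the pre/post still periods is a free parameter of
#'   the method, exposed here rather than hard-coded.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(smooth_ms = 500, window_ms = 400, threshold = 0.2,
                            quiescence_ms = 400) {
  vals <- c(smooth_ms = smooth_ms, window_ms = window_ms,
            threshold = threshold, quiescence_ms = quiescence_ms)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all detector parameters must be positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(
    "<detector_params> smooth %g ms | window %g ms | threshold %g m/s^2 | quiescence %g ms\n",
    x$smooth_ms, x$window_ms, x$threshold, x$quiescence_ms))
  invisible(x)
}

# duration in ms -> span in samples at a given rate
.span_samples <- function(ms, sample_rate) {
  max(1L, as.integer(round(ms / 1000 * sample_rate)))
}

# Rolling max over windows of w consecutive samples (stride 1), computed by
# doubling pmax over shifted copies: O(n log w), no compiled code needed.
.roll_max <- function(x, w) {
  n <- length(x)
  r <- x
  span <- 1L
  while (span < w) {
    s <- min(span, w - span)
    m <- length(r) - s
    r <- pmax(r[seq_len(m)], r[seq_len(m) + s])
    span <- span + s
  }
  r
}

.roll_min <- function(x, w) -.roll_max(-x, w)

# Centred moving average over k samples.  For even k the window is
# [i - floor((k-1)/2), i + ceiling((k-1)/2)].  Where that window would leave
# the trace, it shrinks symmetrically to the largest centred window that fits,
# so the output has the input's length and a constant trace is unchanged.
.roll_mean_centred <- function(x, k) {
  n <- length(x)
  if (k <= 1L) return(x)
  L <- (k - 1L) %/% 2L
  R <- k - 1L - L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  interior <- seq.int(L + 1L, n - R)
  out[interior] <- (cs[interior + R + 1L] - cs[interior - L]) / k
  edges <- c(seq_len(min(L, n)), seq.int(max(1L, n - R + 1L), n))
  for (i in unique(edges)) {
    m <- min(i - 1L, n - i)
    out[i] <- (cs[i + m + 1L] - cs[i - m]) / (2L * m + 1L)
  }
  out
}

#' Smooth a trace with a centred boxcar kernel
#'
#' Replaces each axis by its centred moving average over `smooth_ms`
#' (50 samples at 100 Hz for the 500 ms default), applied per axis
#' independently.  Output length equals input length; near the edges the
#' window shrinks symmetrically, so no padding values are fabricated.
#'
#' @param trace An [accel_trace()].
#' @param params A [detector_params()].
#' @return The smoothed [accel_trace()].
#' @export
smooth_trace <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(params, "detector_params"))
  k <- .span_samples(params$smooth_ms, trace$sample_rate)
  n <- nrow(trace$axes)
  if (k > n) {
    stop("smoothing kernel (", k, " samples) exceeds trace length (", n, ")",
         call. = FALSE)
  }
  sm <- apply(trace$axes, 2L, .roll_mean_centred, k = k)
  accel_trace(sm[, 1L], sm[, 2L], sm[, 3L], trace$sample_rate, trace$limb_label)
}

#' Per-axis sliding-window acceleration ranges
#'
#' For every window start position (stride one sample), the difference between
#' the maximal and minimal acceleration within a `window_ms` window, computed
#' for each movement axis separately.
#'
#' @param trace An [accel_trace()] (normally already smoothed).
#' @param params A [detector_params()].
#' @return A numeric matrix with `n_samples - window_span + 1` rows and
#'   columns `x`, `y`, `z`.
#' @export
window_ranges <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(params, "detector_params"))
  w <- .span_samples(params$window_ms, trace$sample_rate)
  if (w < 2L) stop("window must span at least 2 samples at this sample rate", call. = FALSE)
  n <- nrow(trace$axes)
  if (w > n) stop("window (", w, " samples) exceeds trace length (", n, ")", call. = FALSE)
  out <- vapply(c("x", "y", "z"), function(a) {
    v <- trace$axes[, a]
    .roll_max(v, w) - .roll_min(v, w)
  }, numeric(n - w + 1L))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, c("x", "y", "z")))
  out
}

#' Detect movement events in a smoothed trace
#'
#' A window position is *supra-threshold* when its acceleration range exceeds
#' `threshold` on at least one axis, and *still* when its range is below
#' `threshold` on all axes.  A candidate event is a maximal run of consecutive
#' supra-threshold window positions; it is accepted iff the `quiescence_ms`
#' interval of window positions immediately before its first supra-threshold
#' window and immediately after its last one lies fully inside the trace and
#' contains only still windows.  Accepted events are disjoint and ordered.
#'
#' The event's sample span is the run of window starts plus the window span of
#' the last position (half-open `[start_sample, end_sample)`).  Windows are
#' evaluated only where fully inside the trace: padding would fabricate
#' quiescence at the edges.
#'
#' The caller is expected to pass a smoothed trace (see [smooth_trace()]);
#' [count_movements()] runs the full chain.
#'
#' @param trace A smoothed [accel_trace()].
#' @param params A [detector_params()].
#' @return A data frame of class `movement_events`, one row per accepted
#'   event: `start_sample`, `end_sample` (half-open), `start_s`, `end_s`,
#'   `range_x`, `range_y`, `range_z` (max-minus-min per axis over the event's
#'   samples) and `triggering_axes` (comma-joined subset of `x,y,z` whose
#'   window range exceeded the threshold within the run).
#' @export
detect_movements <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(params, "detector_params"))
  sr <- trace$sample_rate
  w <- .span_samples(params$window_ms, sr)
  q <- .span_samples(params$quiescence_ms, sr)
  n <- nrow(trace$axes)
  empty <- data.frame(start_sample = integer(0), end_sample = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      range_x = numeric(0), range_y = numeric(0),
                      range_z = numeric(0), triggering_axes = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("movement_events", "data.frame")
  if (n < w + 2L * q) {
    warning("trace too short (", n, " samples) for window + 2 x quiescence (",
            w + 2L * q, "); no event can satisfy the quiescence condition",
            call. = FALSE)
    return(empty)
  }
  rng <- window_ranges(trace, params)
  thr <- params$threshold
  above <- (rng[, "x"] > thr) | (rng[, "y"] > thr) | (rng[, "z"] > thr)
  still <- (rng[, "x"] < thr) & (rng[, "y"] < thr) & (rng[, "z"] < thr)
  if (!any(above)) return(empty)

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  first <- starts[runs$values]
  last <- ends[runs$values]
  npos <- length(above)

  keep <- logical(length(first))
  for (j in seq_along(first)) {
    f <- first[j]; l <- last[j]
    keep[j] <- (f - q >= 1L) && (l + q <= npos) &&
      all(still[(f - q):(f - 1L)]) && all(still[(l + 1L):(l + q)])
  }
  first <- first[keep]; last <- last[keep]
  if (!length(first)) return(empty)

  ev <- lapply(seq_along(first), function(j) {
    f <- first[j]; l <- last[j]
    span <- f:(l + w - 1L)
    seg <- trace$axes[span, , drop = FALSE]
    pr <- apply(seg, 2L, function(v) max(v) - min(v))
    trig <- colnames(rng)[apply(rng[f:l, , drop = FALSE], 2L, max) > thr]
    data.frame(start_sample = f, end_sample = l + w, # half-open
               start_s = (f - 1L) / sr, end_s = (l + w - 1L) / sr,
               range_x = pr[["x"]], range_y = pr[["y"]], range_z = pr[["z"]],
               triggering_axes = paste(trig, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ev)
  class(out) <- c("movement_events", "data.frame")
  out
}

#' Count movements in a raw trace
#'
#' Convenience wrapper running the full detection chain: smoothing
#' ([smooth_trace()]) followed by event detection ([detect_movements()]).
#' Because the detection statistic is a within-window range, the count is
#' invariant under adding any constant offset (e.g. gravity) to an axis.
#'
#' @param trace A raw [accel_trace()].
#' @param params A [detector_params()].
#' @param smooth Apply the smoothing stage first (default `TRUE`; set to
#'   `FALSE` if the trace has already been smoothed).
#' @return Integer number of detected movement events.
#' @export
count_movements <- function(trace, params = detector_params(), smooth = TRUE) {
  if (smooth) trace <- smooth_trace(trace, params)
  nrow(detect_movements(trace, params))
}
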