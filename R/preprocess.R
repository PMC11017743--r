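#' Baseline (F0) specification for dF/F0 normalisation
#'
#' Two baseline definitions are supported: `fixed_window` averages the
#' first `window` seconds of each trace (the convention for short
#' recordings that start at rest) and `percentile` takes a low percentile
#' of the whole trace (robust when a recording begins mid-transient).
#' With `clamp_denominator_below_one = TRUE`, an F0 below 1 is replaced by
#' 1 in the denominator only — the numerator always uses the unclamped F0 —
#' preventing aberrant amplification for neurons with very low basal
#' fluorescence.
#'
#' @param method `"fixed_window"` or `"percentile"`.
#' @param window Seconds averaged for `fixed_window` (default 2).
#' @param percentile Percentile in (0, 100) for `percentile` (default 10).
#' @param clamp_denominator_below_one Apply the F0 < 1 denominator clamp.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("fixed_window", "percentile"),
                          window = 2, percentile = 10,
                          clamp_denominator_below_one = TRUE) {
  method <- match.arg(method)
  stopifnot(window > 0, percentile > 0, percentile < 100)
  structure(list(method = method, window = window, percentile = percentile,
                 clamp_denominator_below_one =
                   isTRUE(clamp_denominator_below_one)),
            class = "baseline_spec")
}

#' Subtract a per-frame background signal
#'
#' Subtracts a background fluorescence series (e.g. the mean of a
#' neuron-free background ROI) from every neuron's trace, frame by frame.
#' Values may go negative; downstream dF/F0 handles that via the
#' denominator clamp.
#'
#' @param traces A raw [trace_matrix()].
#' @param background Numeric vector, one value per frame.
#' @return A [trace_matrix()] with the background removed.
#' @export
subtract_background <- function(traces, background) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (length(background) != n_frames(traces)) {
    stop(sprintf("background length (%d) must equal frame count (%d)",
                 length(background), n_frames(traces)), call. = FALSE)
  }
  out <- traces
  out$values <- traces$values -
    matrix(background, n_neurons(traces), n_frames(traces), byrow = TRUE)
  log_op(out, "subtract_background")
}

# trace_matrix invariant requires finite values but clipping is not applied
# here: background-subtracted traces may be negative by design.

#' dF/F0 normalisation
#'
#' Converts raw fluorescence to percent dF/F0 per neuron:
#' `100 * (Ft - F0) / F0`, with F0 computed per [baseline_spec()]. When the
#' denominator clamp is enabled and F0 < 1, the denominator (but not the
#' numerator) is set to 1.
#'
#' @param traces A raw (non-normalised) [trace_matrix()].
#' @param baseline A [baseline_spec()].
#' @return A normalised [trace_matrix()] in percent dF/F0.
#' @export
delta_f_over_f0 <- function(traces, baseline = baseline_spec()) {
  stopifnot(inherits(traces, "trace_matrix"),
            inherits(baseline, "baseline_spec"))
  if (traces$normalized) {
    stop("traces are already dF/F0-normalised", call. = FALSE)
  }
  v <- traces$values
  f0 <- switch(baseline$method,
    fixed_window = {
      w <- max(1L, round(baseline$window * traces$sampling_rate))
      if (w > ncol(v)) {
        stop("baseline window longer than the recording", call. = FALSE)
      }
      rowMeans(v[, seq_len(w), drop = FALSE])
    },
    percentile = apply(v, 1, stats::quantile,
                       probs = baseline$percentile / 100, names = FALSE))
  if (baseline$clamp_denominator_below_one) {
    denom <- pmax(f0, 1)
  } else {
    if (any(f0 == 0)) {
      stop("F0 is zero for neuron(s) ",
           paste(traces$neuron_ids[f0 == 0], collapse = ", "),
           "; enable the denominator clamp or choose another baseline",
           call. = FALSE)
    }
    denom <- f0
  }
  out <- traces
  out$values <- 100 * (v - f0) / denom
  out$normalized <- TRUE
  log_op(out, "delta_f_over_f0", method = baseline$method,
         clamp = baseline$clamp_denominator_below_one)
}

#' Centered moving-average smoothing
#'
#' Smooths each trace with a centered moving average of
#' `round(window * sampling_rate)` frames. The window shrinks at the trace
#' edges (no padding), so no invented samples enter downstream features.
#'
#' @param traces A [trace_matrix()].
#' @param window Window length in seconds; at least one frame.
#' @return A smoothed [trace_matrix()] of identical dimensions.
#' @export
smooth_traces <- function(traces, window = 1) {
  stopifnot(inherits(traces, "trace_matrix"))
  nf <- n_frames(traces)
  w <- round(window * traces$sampling_rate)
  if (w < 1) {
    stop("window must cover at least one frame", call. = FALSE)
  }
  if (w > nf) {
    stop("smoothing window longer than the recording", call. = FALSE)
  }
  lo <- pmax(1L, seq_len(nf) - floor((w - 1) / 2))
  hi <- pmin(nf, seq_len(nf) + floor(w / 2))
  v <- traces$values
  cs <- cbind(0, t(apply(v, 1, cumsum)))
  out <- traces
  out$values <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1L, nrow(v), nf, byrow = TRUE)
  dimnames(out$values) <- dimnames(v)
  log_op(out, "smooth", window_s = window)
}

#' Linear-interpolation resampling
#'
#' Re-grids traces onto a new sampling rate spanning the same time
#' interval, with values linearly interpolated between bracketing source
#' frames. No anti-alias filter is applied; when both smoothing and
#' downsampling are wanted, smooth first ([smooth_traces()]) as the
#' pipeline does for 32 Hz two-photon data before scoring at 3.65 Hz.
#'
#' @param traces A [trace_matrix()] with at least 2 frames.
#' @param target_rate New sampling rate, Hz.
#' @return A [trace_matrix()] at `target_rate`.
#' @export
resample_linear <- function(traces, target_rate) {
  stopifnot(inherits(traces, "trace_matrix"), target_rate > 0)
  nf <- n_frames(traces)
  src_t <- frame_times(nf, traces$sampling_rate)
  span <- src_t[nf]
  n_out <- as.integer(floor(span * target_rate)) + 1L
  if (n_out < 2L) {
    stop("target rate too low: fewer than 2 output frames", call. = FALSE)
  }
  out_t <- frame_times(n_out, target_rate)
  v <- traces$values
  new_v <- matrix(0, nrow(v), n_out)
  for (i in seq_len(nrow(v))) {
    new_v[i, ] <- stats::approx(src_t, v[i, ], xout = out_t)$y
  }
  rownames(new_v) <- rownames(v)
  out <- traces
  out$values <- new_v
  out$sampling_rate <- target_rate
  log_op(out, "resample_linear", target_hz = target_rate)
}

#' Extract a head or tail segment
#'
#' Returns the first or last `n_frames` frames of every trace, e.g. the
#' pre-block head and post-block tail segments used to assemble training
#' sets around a lidocaine event.
#'
#' @param traces A [trace_matrix()].
#' @param which `"first"` or `"last"`.
#' @param n_frames Number of frames to keep.
#' @return A [trace_matrix()] of `n_frames` frames.
#' @export
extract_segment <- function(traces, which = c("first", "last"), n_frames) {
  which <- match.arg(which)
  stopifnot(inherits(traces, "trace_matrix"))
  nf <- ncol(traces$values)
  if (n_frames > nf) {
    stop(sprintf("requested %d frames but the recording has %d",
                 n_frames, nf), call. = FALSE)
  }
  idx <- if (which == "first") seq_len(n_frames) else (nf - n_frames + 1L):nf
  out <- traces
  out$values <- traces$values[, idx, drop = FALSE]
  log_op(out, "extract_segment", which = which, n = n_frames)
}
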