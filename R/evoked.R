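#' Stimulus protocol
#'
#' Ordered, non-overlapping stimulus epochs (e.g. electrical pulses at the
#' sciatic nerve, or Peltier heat ramps — only the epoch timestamps matter
#' here).
#'
#' @param epochs Data frame with numeric columns `onset` and `offset`
#'   (seconds), ordered and non-overlapping.
#' @param modality Free-text stimulus modality.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(epochs, modality = "unspecified") {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("onset", "offset") %in% names(epochs)),
            all(epochs$offset > epochs$onset))
  if (nrow(epochs) > 1L) {
    o <- order(epochs$onset)
    epochs <- epochs[o, ]
    if (any(epochs$onset[-1L] < epochs$offset[-nrow(epochs)])) {
      stop("stimulus epochs must not overlap", call. = FALSE)
    }
  }
  rownames(epochs) <- NULL
  structure(list(epochs = epochs, modality = modality),
            class = "stimulus_protocol")
}

#' Evoked-response detection rule
#'
#' Baseline-referenced threshold rule for stimulus-evoked transients: a
#' response is positive when the smoothed trace's peak during stimulation
#' exceeds `Fb + (Fb_max - Fb) * x`, where Fb and Fb_max are the mean and
#' maximum dF/F0 over a pre-stimulus baseline window, and the contiguous
#' time above threshold is at least `min_duration` (very brief excursions
#' are excluded, given the slow indicator decay).
#'
#' @param x Threshold multiplier; values in `[2, 3]` give reliable
#'   detection (default 2.5, the midpoint), chosen per run depending on
#'   baseline stability. Values outside that range warn.
#' @param smoothing_window Pre-detection moving-average window, seconds.
#' @param min_duration Minimum contiguous suprathreshold time, seconds.
#' @param baseline_start_offset Baseline starts this long after the
#'   recording start, seconds.
#' @param baseline_end_offset Baseline ends this long before stimulus
#'   onset, seconds.
#' @param post_offset_grace Seconds after epoch offset still searched for
#'   the (lagged) peak of a slow indicator.
#' @return An object of class `evoked_rule`.
#' @export
evoked_rule <- function(x = 2.5, smoothing_window = 1, min_duration = 0.5,
                        baseline_start_offset = 1, baseline_end_offset = 1,
                        post_offset_grace = 1) {
  stopifnot(x > 0, smoothing_window >= 0, min_duration >= 0,
            baseline_start_offset >= 0, baseline_end_offset >= 0,
            post_offset_grace >= 0)
  if (x < 2 || x > 3) {
    warning("x outside the recommended [2, 3] range", call. = FALSE)
  }
  structure(list(x = x, smoothing_window = smoothing_window,
                 min_duration = min_duration,
                 baseline_start_offset = baseline_start_offset,
                 baseline_end_offset = baseline_end_offset,
                 post_offset_grace = post_offset_grace),
            class = "evoked_rule")
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Detect evoked responses
#'
#' Applies the [evoked_rule()] per neuron and stimulus epoch: the trace is
#' smoothed, Fb/Fb_max are computed over the baseline window (from
#' `baseline_start_offset` after recording start to `baseline_end_offset`
#' before the epoch onset), and the epoch is positive when the peak within
#' `[onset, offset + grace]` exceeds `Fb + (Fb_max - Fb) * x` with at
#' least `min_duration` of contiguous suprathreshold time. A flat baseline
#' (Fb_max = Fb) degenerates to the threshold Fb itself. Epochs outside
#' the recording are skipped with a message.
#'
#' @param traces A normalised [trace_matrix()].
#' @param protocol A [stimulus_protocol()].
#' @param rule An [evoked_rule()].
#' @return A data frame with one row per neuron x epoch: `neuron_id`,
#'   `epoch`, `onset`, `offset`, `fb`, `fb_max`, `threshold`, `peak`,
#'   `duration_above` (seconds) and `positive`.
#' @export
detect_evoked <- function(traces, protocol, rule = evoked_rule()) {
  stopifnot(inherits(traces, "trace_matrix"),
            inherits(protocol, "stimulus_protocol"),
            inherits(rule, "evoked_rule"))
  assert_normalized(traces, "detect_evoked")
  sm <- if (rule$smoothing_window > 0 &&
            round(rule$smoothing_window * traces$sampling_rate) >= 1) {
    smooth_traces(traces, rule$smoothing_window)
  } else {
    traces
  }
  nf <- n_frames(sm)
  times <- frame_times(nf, sm$sampling_rate)
  rows <- list()
  for (e in seq_len(nrow(protocol$epochs))) {
    onset <- protocol$epochs$onset[e]
    offset <- protocol$epochs$offset[e]
    if (onset > times[nf]) {
      message(sprintf("epoch %d (onset %.2f s) lies outside the recording; skipped",
                      e, onset))
      next
    }
    b_idx <- which(times >= rule$baseline_start_offset &
                     times <= onset - rule$baseline_end_offset)
    if (!length(b_idx)) {
      stop(sprintf(
        "epoch %d: empty baseline window (onset %.2f s too early for offsets %g + %g s)",
        e, onset, rule$baseline_start_offset, rule$baseline_end_offset),
        call. = FALSE)
    }
    w_idx <- which(times >= onset &
                     times <= offset + rule$post_offset_grace)
    if (!length(w_idx)) {
      message(sprintf("epoch %d has no frames within the recording; skipped", e))
      next
    }
    for (i in seq_len(n_neurons(sm))) {
      y <- sm$values[i, ]
      fb <- mean(y[b_idx])
      fb_max <- max(y[b_idx])
      thr <- fb + (fb_max - fb) * rule$x
      seg <- y[w_idx]
      peak <- max(seg)
      dur <- longest_run(seg > thr) / sm$sampling_rate
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = sm$neuron_ids[i], epoch = e, onset = onset,
        offset = offset, fb = fb, fb_max = fb_max, threshold = thr,
        peak = peak, duration_above = dur,
        positive = peak > thr && dur >= rule$min_duration,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(neuron_id = character(0), epoch = integer(0),
                      onset = numeric(0), offset = numeric(0),
                      fb = numeric(0), fb_max = numeric(0),
                      threshold = numeric(0), peak = numeric(0),
                      duration_above = numeric(0), positive = logical(0)))
  }
  do.call(rbind, rows)
}

#' Summarise evoked responses per neuron
#'
#' A neuron is a responder when it was positive in at least `quorum`
#' epochs (default 1).
#'
#' @param table Output of [detect_evoked()].
#' @param quorum Minimum number of positive epochs.
#' @return Data frame: `neuron_id`, `n_epochs`, `n_positive`,
#'   `response_fraction`, `responder`.
#' @export
summarize_evoked <- function(table, quorum = 1) {
  stopifnot(quorum >= 1)
  if (!nrow(table)) {
    return(data.frame(neuron_id = character(0), n_epochs = integer(0),
                      n_positive = integer(0),
                      response_fraction = numeric(0),
                      responder = logical(0)))
  }
  out <- do.call(rbind, lapply(split(table, table$neuron_id), function(d) {
    data.frame(neuron_id = d$neuron_id[1], n_epochs = nrow(d),
               n_positive = sum(d$positive),
               response_fraction = mean(d$positive),
               responder = sum(d$positive) >= quorum,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
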